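#' Global Metal Protein Association (GMPA) score
#'
#' The GMPA score of a protein/metal pair is the hypergeometric upper-tail
#' probability of seeing the protein in at least its observed number of
#' metal-peak fractions, were its occurrences scattered uniformly at random
#' over the fraction space:
#'
#' \deqn{G = \sum_{n = f_{pm}}^{\min(f_p, f_m)}
#'   \frac{\binom{f_m}{n} \binom{f - f_m}{f_p - n}}{\binom{f}{f_p}}
#'   = P(X \ge f_{pm}), \quad X \sim \mathrm{Hypergeom}(f, f_m, f_p)}
#'
#' where `f` is the number of fractions in the analysis universe, `f_m` the
#' number inside peaks of the metal, `f_p` the number in which the protein
#' was observed and `f_pm` the overlap. Low scores mean the co-occurrence
#' is unlikely by chance. Computed through the numerically stable
#' hypergeometric survival function ([stats::phyper()]), never naive
#' factorials; for very strong associations the probability underflows
#' double precision, so the returned score is floored at `floor` and the
#' companion [gmpa_ln_score()] should be used for any work on the log
#' scale.
#'
#' @param f Total fractions in the analysis universe.
#' @param f_m Fractions inside peaks of the metal (`0 <= f_m <= f`).
#' @param f_p Fractions in which the protein was observed (`0 <= f_p <= f`).
#' @param f_pm Overlap count; must satisfy
#'   `max(0, f_p - (f - f_m)) <= f_pm <= min(f_p, f_m)`.
#' @param floor Positive lower bound applied to the score (default 1e-300).
#' @return Score(s) in `(0, 1]`. All arguments recycle.
#' @examples
#' gmpa_score(10, 4, 3, 3)  # 4/120
#' gmpa_score(10, 4, 3, 0)  # 1: P(X >= 0)
#' @export
gmpa_score <- function(f, f_m, f_p, f_pm, floor = 1e-300) {
  check_gmpa_counts(f, f_m, f_p, f_pm)
  pmin(1, pmax(floor, stats::phyper(f_pm - 1, f_m, f - f_m, f_p,
                                    lower.tail = FALSE)))
}

#' Natural-log GMPA score
#'
#' Log-scale companion of [gmpa_score()], computed with `log.p = TRUE` so
#' it stays accurate far below the double-precision underflow point, then
#' floored at `log(floor)` so downstream regression on ln-scores is
#' well-defined and consistent with the floored linear-scale score.
#'
#' @inheritParams gmpa_score
#' @return `ln` score(s) in `[log(floor), 0]`.
#' @export
gmpa_ln_score <- function(f, f_m, f_p, f_pm, floor = 1e-300) {
  check_gmpa_counts(f, f_m, f_p, f_pm)
  pmin(0, pmax(log(floor), stats::phyper(f_pm - 1, f_m, f - f_m, f_p,
                                         lower.tail = FALSE, log.p = TRUE)))
}

check_gmpa_counts <- function(f, f_m, f_p, f_pm) {
  if (any(f_m > f)) gmpa_error("gmpa_domain_error", "requires f_m <= f")
  if (any(f_p > f)) gmpa_error("gmpa_domain_error", "requires f_p <= f")
  if (any(f_m < 0 | f_p < 0 | f < 0)) {
    gmpa_error("gmpa_domain_error", "counts must be non-negative")
  }
  if (any(f_pm > pmin(f_p, f_m))) {
    gmpa_error("gmpa_domain_error", "requires f_pm <= min(f_p, f_m)")
  }
  if (any(f_pm < pmax(0, f_p - (f - f_m)))) {
    gmpa_error("gmpa_domain_error", "requires f_pm >= max(0, f_p - (f - f_m))")
  }
  invisible(TRUE)
}

#' Score every protein against every metal's peaks
#'
#' Computes the GMPA quadruple and score for each (protein, metal) pair.
#' The analysis universe `f` is the set of fraction columns of the presence
#' matrix; each metal's peak fractions are intersected with that universe,
#' so `f` is identical across all results and `f_m` identical within a
#' metal.
#'
#' @param presence Logical protein x fraction matrix from
#'   [build_presence_matrix()].
#' @param peaksets Named list metal -> `gmpa_peakset`.
#' @param floor Underflow floor passed to the score functions.
#' @return Data frame with one row per (protein, metal): `protein_id`,
#'   `metal`, `f`, `f_m`, `f_p`, `f_pm`, `score`, `ln_score`, matching the
#'   `gmpa_scores.tsv` interchange format.
#' @export
score_all <- function(presence, peaksets, floor = 1e-300) {
  universe <- colnames(presence)
  f <- length(universe)
  f_p <- rowSums(presence)
  out <- lapply(names(peaksets), function(metal) {
    peak_cols <- intersect(peaksets[[metal]]$peak_fraction_ids, universe)
    f_m <- length(peak_cols)
    f_pm <- if (f_m > 0) rowSums(presence[, peak_cols, drop = FALSE]) else
      rep(0L, nrow(presence))
    data.frame(protein_id = rownames(presence), metal = metal, f = f,
               f_m = f_m, f_p = as.integer(f_p), f_pm = as.integer(f_pm),
               score = gmpa_score(f, f_m, f_p, f_pm, floor = floor),
               ln_score = gmpa_ln_score(f, f_m, f_p, f_pm, floor = floor),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
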