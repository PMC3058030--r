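#' @title Exponential significance curves in GMPA score/occurrence space
#' @description
#' Because occurrence frequency dominates the GMPA score, raw scores are
#' not compared to a single cutoff. Instead each metal gets an exponential
#' *significance curve* through (occurrences, score) space,
#' `curve(occ) = exp(a + c * b * occ)`, where `(a, b)` is a least-squares
#' exponential regression of score on occurrences over all proteins of the
#' metal and `c > 0` rescales only the exponent. For metals with known
#' metalloproteins the curve is anchored so that every usable known
#' reference falls on or below it; for other metals `c` is extrapolated as
#' the mean of the anchored metals' ratios. Proteins at or below their
#' metal's curve, with at least `min_occurrences` fraction occurrences,
#' are deemed significantly metal-associated and passed to clustering.
#' @name significance
NULL

new_curve <- function(metal, intercept_a, exponent_b, ratio_c, source) {
  structure(list(metal = metal, intercept_a = intercept_a,
                 exponent_b = exponent_b, ratio_c = ratio_c, source = source),
            class = "gmpa_curve")
}

#' @export
print.gmpa_curve <- function(x, ...) {
  cat(sprintf("%s significance curve (%s): exp(%.4g %+.4g * occ), ratio c = %.4g\n",
              x$metal, x$source, x$intercept_a, x$ratio_c * x$exponent_b,
              x$ratio_c))
  invisible(x)
}

#' Evaluate a significance curve
#'
#' @param curve A `gmpa_curve`.
#' @param occ Occurrence count(s).
#' @param log Return the natural log of the curve value?
#' @return `exp(a + c * b * occ)` (or its log).
#' @export
curve_value <- function(curve, occ, log = FALSE) {
  v <- curve$intercept_a + curve$ratio_c * curve$exponent_b * occ
  if (log) v else exp(v)
}

#' Fit the per-metal exponential regression of GMPA score on occurrences
#'
#' Ordinary least squares of `ln(score)` on `f_p` over all proteins of one
#' metal (the regression curve drawn "through all points"), using the
#' floored ln-score so underflowed associations still contribute finite
#' values.
#'
#' @param results GMPA result data frame for a single metal (rows with
#'   `f_p >= 1` are used; at least 3 required).
#' @return Named numeric `c(intercept_a =, exponent_b =)`.
#' @export
fit_regression <- function(results) {
  pts <- results[results$f_p >= 1, ]
  if (nrow(pts) < 3) {
    value_error("need at least 3 proteins with f_p >= 1 to fit a regression (have %d)",
                nrow(pts))
  }
  if (stats::var(pts$f_p) == 0) {
    value_error("all proteins have identical occurrence counts; regression undefined")
  }
  fit <- stats::lm.fit(cbind(1, pts$f_p), pts$ln_score)
  c(intercept_a = unname(fit$coefficients[1]),
    exponent_b = unname(fit$coefficients[2]))
}

#' Anchor a significance curve on known metalloproteins
#'
#' For a metal with known metalloprotein (subunit) references, the curve
#' keeps the regression intercept and scales the regression exponent by
#' `ratio_c`, chosen as the minimum over qualifying references `r` of
#' `(ln(score_r) - a) / (b * f_p_r)` and clipped into `(0, c_max]`. The
#' minimum guarantees that every qualifying reference lies on or below the
#' curve and therefore survives [filter_significant()]. References observed
#' in fewer than `min_occurrences` fractions are excluded from the
#' anchoring — too few occurrences to establish significance — and are not
#' guaranteed to be captured.
#'
#' @param results GMPA result data frame for the metal.
#' @param regression `(intercept_a, exponent_b)` from [fit_regression()];
#'   `exponent_b` must be negative (scores must decay with occurrences).
#' @param reference_ids Character vector of known metalloprotein IDs for
#'   this metal.
#' @param min_occurrences Minimum `f_p` for a reference to qualify
#'   (default 10).
#' @param c_max Upper clip for `ratio_c` (default 2): the significance
#'   curve is allowed to fall at most twice as fast as the regression.
#'   References with extremely low scores would otherwise drive the ratio
#'   arbitrarily high, over-fitting the steepest reference and making the
#'   ratio useless for extrapolation to other metals; clipping downward
#'   only ever raises the curve, so the reference-capture guarantee is
#'   unaffected.
#' @return A `gmpa_curve` with `source = "reference"`.
#' @export
set_reference_curve <- function(results, regression, reference_ids,
                                min_occurrences = 10, c_max = 2) {
  a <- regression[["intercept_a"]]
  b <- regression[["exponent_b"]]
  refs <- results[results$protein_id %in% reference_ids &
                    results$f_p >= min_occurrences, ]
  if (nrow(refs) == 0) {
    value_error(paste0("no reference protein with >= %d occurrences and a GMPA ",
                       "result for %s; use extrapolate_curve()"),
                min_occurrences, results$metal[1])
  }
  if (!(b < 0)) {
    value_error("regression exponent must be negative to anchor a curve (b = %g)", b)
  }
  ratios <- (refs$ln_score - a) / (b * refs$f_p)
  ratio_c <- min(ratios)
  ratio_c <- min(max(ratio_c, .Machine$double.eps), c_max)
  new_curve(results$metal[1], a, b, ratio_c, "reference")
}

#' Extrapolate a significance curve from reference-anchored metals
#'
#' For metals with few or no known metalloproteins, the exponent ratio is
#' borrowed as the arithmetic mean of the `ratio_c` of the reference-
#' anchored curves, applied to this metal's own regression.
#'
#' @param regression This metal's `(intercept_a, exponent_b)`.
#' @param reference_curves Nonempty list of `gmpa_curve` objects (typically
#'   all `source = "reference"` curves).
#' @param metal Metal symbol for the new curve.
#' @return A `gmpa_curve` with `source = "extrapolated"`.
#' @export
extrapolate_curve <- function(regression, reference_curves, metal = NA_character_) {
  if (length(reference_curves) == 0) {
    value_error("extrapolate_curve needs at least one reference curve")
  }
  ratio_c <- mean(vapply(reference_curves, `[[`, 0.0, "ratio_c"))
  new_curve(metal, regression[["intercept_a"]], regression[["exponent_b"]],
            ratio_c, "extrapolated")
}

#' Hand-set a significance curve
#'
#' Escape hatch mirroring manually drawn curves: all three parameters are
#' supplied directly.
#'
#' @param metal Metal symbol.
#' @param intercept_a,exponent_b,ratio_c Curve parameters (`ratio_c > 0`).
#' @return A `gmpa_curve` with `source = "manual"`.
#' @export
manual_curve <- function(metal, intercept_a, exponent_b, ratio_c = 1) {
  if (ratio_c <= 0) value_error("ratio_c must be positive")
  new_curve(metal, intercept_a, exponent_b, ratio_c, "manual")
}

#' Select significantly metal-associated proteins
#'
#' A protein is significant for a metal when its GMPA score is at or below
#' the metal's significance curve at its occurrence count (boundary
#' inclusive) **and** it occurs in at least `min_occurrences` fractions —
#' the absolute occurrence cutoff that removes proteins seen too rarely
#' for any co-occurrence signal to be trusted. The comparison is done in
#' log space (floored ln-score vs the curve's log value) so it is exact
#' even where the linear-scale score underflowed.
#'
#' @param results GMPA result data frame for the curve's metal.
#' @param curve A `gmpa_curve`.
#' @param min_occurrences Absolute occurrence cutoff (default 10).
#' @return Character vector of significant protein IDs (sorted).
#' @export
filter_significant <- function(results, curve, min_occurrences = 10) {
  ok <- results$ln_score <= curve_value(curve, results$f_p, log = TRUE) &
    results$f_p >= min_occurrences
  sort(results$protein_id[ok])
}

#' Load a known-metalloprotein reference table
#'
#' @param path TSV with columns `metal`, `protein_id`.
#' @return Named list metal -> character vector of protein IDs.
#' @export
load_references <- function(path) {
  df <- read_tsv(path, required = c("metal", "protein_id"))
  lapply(split(as.character(df$protein_id), as.character(df$metal)), unique)
}
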