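#' Greedy set cover of a metal's peaks by proteins
#'
#' How few proteins could explain all of a metal's peaks? Each peak region
#' is a set element; a protein covers a peak when it is observed in at
#' least one of the peak's fractions. The classical greedy approximation
#' repeatedly picks the candidate covering the most still-uncovered peaks
#' (guaranteed within `1 + ln(u)` of the optimum for `u` peaks), yielding a
#' lower-bound style sanity check on the clustering-based metalloprotein
#' count. Ties are broken deterministically: lower GMPA score first (when
#' `scores` is given), then lexicographic protein ID.
#'
#' @param presence Logical protein x fraction matrix.
#' @param peakset A `gmpa_peakset` for the metal.
#' @param candidates Character vector of candidate protein IDs (subset of
#'   the matrix rows), e.g. all observed or only significant proteins.
#' @param scores Optional named numeric vector of GMPA scores used for tie
#'   breaking.
#' @return List of class `gmpa_cover`: `metal`, `chosen_proteins` (in
#'   selection order), `covered` (peak_id -> covering protein),
#'   `cover_size`, `uncovered_peaks` (peaks no candidate touches).
#' @export
greedy_cover <- function(presence, peakset, candidates, scores = NULL) {
  bad <- setdiff(candidates, rownames(presence))
  if (length(bad) > 0) {
    value_error("candidate protein(s) not in presence matrix: %s",
                paste(utils::head(bad, 5), collapse = ", "))
  }
  candidates <- sort(unique(candidates))
  peak_ids <- vapply(peakset$regions, `[[`, "", "peak_id")
  # candidate x peak incidence: does the protein touch >= 1 peak fraction?
  inc <- matrix(FALSE, length(candidates), length(peak_ids),
                dimnames = list(candidates, peak_ids))
  for (j in seq_along(peak_ids)) {
    cols <- intersect(peakset$regions[[j]]$fraction_ids, colnames(presence))
    if (length(cols) > 0) {
      inc[, j] <- rowSums(presence[candidates, cols, drop = FALSE]) > 0
    }
  }
  uncovered <- peak_ids[colSums(inc) == 0]
  remaining <- setdiff(peak_ids, uncovered)
  chosen <- character(0)
  covered <- stats::setNames(character(0), character(0))
  while (length(remaining) > 0) {
    gain <- rowSums(inc[, remaining, drop = FALSE])
    best <- max(gain)
    if (best == 0) break
    cand <- candidates[gain == best]
    if (!is.null(scores)) {
      s <- scores[cand]
      s[is.na(s)] <- Inf
      cand <- cand[order(s, cand)]
    }
    pick <- cand[1]
    newly <- remaining[inc[pick, remaining]]
    covered[newly] <- pick
    chosen <- c(chosen, pick)
    remaining <- setdiff(remaining, newly)
  }
  structure(list(metal = peakset$metal, chosen_proteins = chosen,
                 covered = covered, cover_size = length(chosen),
                 uncovered_peaks = uncovered),
            class = "gmpa_cover")
}

#' @export
print.gmpa_cover <- function(x, ...) {
  cat(sprintf("%s: %d protein(s) cover %d peak(s); %d peak(s) uncoverable\n",
              x$metal, x$cover_size, length(x$covered), length(x$uncovered_peaks)))
  invisible(x)
}
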