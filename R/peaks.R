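#' @title Metal-peak fraction regions
#' @description
#' A *metal peak* is a contiguous run (in elution order, within one
#' separation) of at least two fractions whose concentrations for a metal
#' stand substantially above the surrounding baseline in every ICP-MS
#' technical replicate. Manually curated region tables are the primary
#' path; [detect_peaks()] formalizes the visual rule for automated use.
#'
#' A `gmpa_peakset` holds, for one metal, a list of regions
#' (`peak_id`, `metal`, `separation_id`, `fraction_ids`) plus the derived
#' union `peak_fraction_ids`.
#' @name peaks
NULL

new_peakset <- function(metal, regions) {
  structure(list(
    metal = metal,
    regions = regions,
    peak_fraction_ids = unique(unlist(lapply(regions, `[[`, "fraction_ids"),
                                      use.names = FALSE))
  ), class = "gmpa_peakset")
}

#' @export
print.gmpa_peakset <- function(x, ...) {
  cat(sprintf("peak set for %s: %d region(s), %d fraction(s)\n",
              x$metal, length(x$regions), length(x$peak_fraction_ids)))
  invisible(x)
}

# Check one region's contiguity within its separation; returns the gap
# order_index values on failure so errors can name them.
check_region_contiguous <- function(fraction_ids, fractions, peak_id, separation_id) {
  idx <- match(fraction_ids, fractions$fraction_id)
  if (anyNA(idx)) {
    validation_error("peak %s references unknown fraction(s): %s", peak_id,
                     paste(fraction_ids[is.na(idx)], collapse = ", "))
  }
  seps <- fractions$separation_id[idx]
  if (any(seps != separation_id)) {
    validation_error("peak %s: fraction(s) outside separation %s: %s",
                     peak_id, separation_id,
                     paste(fraction_ids[seps != separation_id], collapse = ", "))
  }
  oi <- sort(fractions$order_index[idx])
  if (length(oi) < 2) {
    validation_error("peak %s: a metal peak needs at least 2 fractions", peak_id)
  }
  full <- seq(oi[1], oi[length(oi)])
  gaps <- setdiff(full, oi)
  if (length(gaps) > 0) {
    validation_error("peak %s: fractions not contiguous, missing order_index %s",
                     peak_id, paste(gaps, collapse = ", "))
  }
  invisible(oi)
}

#' Load manually curated metal-peak regions
#'
#' Reads a peak region table (one row per member fraction: `peak_id`,
#' `metal`, `separation_id`, `fraction_id`), validates that each region is
#' a contiguous elution-order run of at least two fractions confined to one
#' separation, and that same-metal regions within a separation are
#' disjoint.
#'
#' @param peaks_file TSV path.
#' @param fractions Fraction table the regions refer to.
#' @return Named list, metal symbol -> `gmpa_peakset`.
#' @export
load_peak_regions <- function(peaks_file, fractions) {
  df <- read_tsv(peaks_file,
                 required = c("peak_id", "metal", "separation_id", "fraction_id"))
  df$peak_id <- as.character(df$peak_id)
  df$metal <- as.character(df$metal)
  df$separation_id <- as.character(df$separation_id)
  df$fraction_id <- as.character(df$fraction_id)
  peaksets_from_df(df, fractions)
}

peaksets_from_df <- function(df, fractions) {
  out <- list()
  for (metal in sort(unique(df$metal))) {
    sub <- df[df$metal == metal, ]
    regions <- lapply(split(sub, sub$peak_id), function(p) {
      sep <- unique(p$separation_id)
      if (length(sep) != 1) {
        validation_error("peak %s spans multiple separations: %s",
                         p$peak_id[1], paste(sep, collapse = ", "))
      }
      oi <- check_region_contiguous(p$fraction_id, fractions, p$peak_id[1], sep)
      idx <- match(p$fraction_id, fractions$fraction_id)
      list(peak_id = p$peak_id[1], metal = metal, separation_id = sep,
           fraction_ids = p$fraction_id[order(fractions$order_index[idx])])
    })
    names(regions) <- NULL
    # same-metal regions within one separation must not share fractions
    for (sep in unique(vapply(regions, `[[`, "", "separation_id"))) {
      ids <- unlist(lapply(regions[vapply(regions, `[[`, "", "separation_id") == sep],
                           `[[`, "fraction_ids"))
      if (anyDuplicated(ids)) {
        validation_error("overlapping %s peak regions in separation %s (fraction %s)",
                         metal, sep, ids[duplicated(ids)][1])
      }
    }
    out[[metal]] <- new_peakset(metal, regions)
  }
  out
}

#' Write peak sets to the one-row-per-member-fraction TSV format
#'
#' @param peaksets Named list of `gmpa_peakset` (as from [load_peak_regions()]
#'   or [detect_peaks()]).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_peak_regions <- function(peaksets, path) {
  rows <- lapply(peaksets, function(ps) {
    do.call(rbind, lapply(ps$regions, function(r) {
      data.frame(peak_id = r$peak_id, metal = r$metal,
                 separation_id = r$separation_id, fraction_id = r$fraction_ids,
                 stringsAsFactors = FALSE)
    }))
  })
  df <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(df)) {
    df <- data.frame(peak_id = character(), metal = character(),
                     separation_id = character(), fraction_id = character())
  }
  rownames(df) <- NULL
  write_tsv(df[order(df$metal, df$peak_id), ], path)
}

#' Detect metal peaks by a replicate-consistent fold-over-baseline rule
#'
#' Formalizes the visual peak-calling rule: within each separation, a
#' fraction is flagged when **every** technical replicate's concentration
#' exceeds `fold` times that replicate's local background. The background
#' is the median of that replicate's concentrations over the `window`
#' nearest unflagged fractions on each side of the candidate (the
#' candidate itself excluded), taking the smaller of the two side medians
#' — at a peak edge one side always looks into clean baseline, so a peak
#' cannot shelter itself inside its own window. Because a wide peak could
#' still contaminate both sides, flagging iterates to a fixpoint: flagged
#' fractions are removed from every background window and the synchronous
#' sweep repeats until no new fraction is flagged. Maximal contiguous
#' flagged runs of at least `min_len` fractions become peak regions.
#'
#' Raising `fold` never adds a flagged fraction. Peaks never span
#' separations.
#'
#' @param metals Metal measurement data frame.
#' @param fractions Fraction table.
#' @param metal Metal symbol to analyse (must occur in `metals`).
#' @param fold Fold-over-background threshold (> 1 sensible; default 3).
#' @param window Number of neighbouring fractions per background side
#'   window; odd, >= 3 (default 5). Peaks wider than about `2 * window`
#'   cannot raise their centres above their own shoulders and may be
#'   missed; choose `window` at least as large as the widest expected
#'   peak.
#' @param min_len Minimum region length in fractions (default 2, the
#'   minimum for a peak by definition).
#' @return A `gmpa_peakset` for `metal` (possibly with zero regions).
#' @export
detect_peaks <- function(metals, fractions, metal, fold = 3.0, window = 5L,
                         min_len = 2L) {
  if (!metal %in% metals$metal) {
    value_error("no measurements for metal '%s'", metal)
  }
  if (window < 3 || window %% 2 == 0) value_error("window must be odd and >= 3")
  sub <- metals[metals$metal == metal, ]
  regions <- list()
  for (sep in sort(unique(fractions$separation_id))) {
    fr <- fractions[fractions$separation_id == sep, ]
    fr <- fr[order(fr$order_index), ]
    n <- nrow(fr)
    if (n < min_len) next
    ms <- sub[sub$fraction_id %in% fr$fraction_id, ]
    if (nrow(ms) == 0) next
    reps <- sort(unique(ms$replicate))
    conc <- matrix(NA_real_, nrow = length(reps), ncol = n,
                   dimnames = list(NULL, fr$fraction_id))
    conc[cbind(match(ms$replicate, reps), match(ms$fraction_id, fr$fraction_id))] <-
      ms$concentration
    flagged <- flag_fixpoint(conc, fold, window)
    # contiguous flagged runs of >= min_len, in elution order
    r <- rle(flagged)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    k <- 0
    for (i in which(r$values & r$lengths >= min_len)) {
      k <- k + 1
      ids <- fr$fraction_id[starts[i]:ends[i]]
      regions[[length(regions) + 1]] <- list(
        peak_id = sprintf("%s_%s_p%d", metal, sep, k), metal = metal,
        separation_id = sep, fraction_ids = ids)
    }
  }
  new_peakset(metal, regions)
}

# Iterated flagging over one separation's replicate x position matrix.
# Sweeps are synchronous: each pass evaluates every fraction against the
# previous pass's flag set, so the result does not depend on scan order.
# Background per replicate = min over the two sides of the median of the
# `window` nearest unflagged fractions on that side (empty sides ignored).
flag_fixpoint <- function(conc, fold, window) {
  n <- ncol(conc)
  flagged <- rep(FALSE, n)
  repeat {
    new_flagged <- flagged
    pool <- which(!flagged)
    for (i in seq_len(n)) {
      if (flagged[i]) next
      left <- rev(pool[pool < i])
      right <- pool[pool > i]
      left <- left[seq_len(min(window, length(left)))]
      right <- right[seq_len(min(window, length(right)))]
      if (length(left) + length(right) == 0) next
      above <- TRUE
      for (r in seq_len(nrow(conc))) {
        meds <- c(if (length(left) > 0) stats::median(conc[r, left], na.rm = TRUE),
                  if (length(right) > 0) stats::median(conc[r, right], na.rm = TRUE))
        bg <- min(meds, na.rm = TRUE)
        x <- conc[r, i]
        if (is.na(x) || !is.finite(bg) || !(x > fold * bg)) { above <- FALSE; break }
      }
      if (above) new_flagged[i] <- TRUE
    }
    if (identical(new_flagged, flagged)) break
    flagged <- new_flagged
  }
  flagged
}

#' Count a metal's peak fractions within an analysis universe
#'
#' The count `f_m` used by the GMPA score: the number of fractions inside
#' any peak of the metal, intersected with the fraction universe actually
#' analysed.
#'
#' @param peakset A `gmpa_peakset`.
#' @param universe Character vector of fraction IDs defining the universe.
#' @return Integer count.
#' @export
peak_fraction_count <- function(peakset, universe) {
  length(intersect(peakset$peak_fraction_ids, universe))
}
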