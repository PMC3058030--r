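#' @title End-to-end GMPA analysis pipeline
#' @description
#' Orchestrates the stages: two-peptide inclusion filter, Boolean presence
#' matrix, metal peaks (manual regions when provided, otherwise automatic
#' detection), GMPA scoring, significance-curve fitting and filtering,
#' co-occurrence clustering with core regions, greedy peak set cover, and
#' (when annotation inputs are given) the InterPro-Metal classifier. Every
#' stage logs its input/output counts and writes plain-TSV outputs so any
#' stage can be re-run independently.
#' @name pipeline
NULL

log_stage <- function(verbose, fmt, ...) {
  if (verbose) message(sprintf(paste0("[gmpa] ", fmt), ...))
}

#' Analyse an in-memory experiment
#'
#' The computational core of [run_pipeline()], operating on an experiment
#' bundle and peak sets already in memory and returning all intermediate
#' results. Deterministic: no randomness anywhere downstream of the
#' inputs.
#'
#' Per metal, the significance curve is anchored on the supplied known
#' metalloprotein references where at least one reference qualifies
#' (observed with a GMPA result and at least `min_occurrences`
#' occurrences, with a decaying regression); metals without usable
#' references borrow the mean exponent ratio of the anchored metals; if no
#' metal can be anchored at all, the regression curve itself is used
#' (ratio 1).
#'
#' @param experiment A `gmpa_experiment`.
#' @param peaksets Named list metal -> `gmpa_peakset`.
#' @param references Optional named list metal -> character vector of known
#'   metalloprotein (subunit) IDs.
#' @param min_peptides Dataset-wide inclusion filter (default 2).
#' @param min_occurrences Absolute occurrence cutoff for significance and
#'   reference qualification (default 10).
#' @param min_cluster_size,deep_split,cut_height_fraction Clustering
#'   parameters, see [cluster_proteins()].
#' @param setcover_candidates `"significant"` (default) or `"all"`: which
#'   proteins may cover peaks.
#' @param verbose Log one line per stage?
#' @return List with `presence`, `scores`, `curves`, `significant`,
#'   `reports`, `covers`, and the per-metal `summary` data frame
#'   (`metal`, `known_subunits_total`, `known_observed`,
#'   `known_meeting_significance`, `proteins_clustered`, `clusters_total`,
#'   `clusters_with_known`, `cover_size`, `n_uncovered_peaks`).
#' @export
analyze_experiment <- function(experiment, peaksets, references = NULL,
                               min_peptides = 2, min_occurrences = 10,
                               min_cluster_size = 3, deep_split = 2,
                               cut_height_fraction = 0.99,
                               setcover_candidates = c("significant", "all"),
                               verbose = FALSE) {
  setcover_candidates <- match.arg(setcover_candidates)
  obs <- filter_proteins(experiment$observations, min_peptides = min_peptides)
  log_stage(verbose, "inclusion filter (>= %d peptides): %d -> %d proteins",
            min_peptides, length(unique(experiment$observations$protein_id)),
            length(unique(obs$protein_id)))
  presence <- build_presence_matrix(obs, experiment$fractions)
  log_stage(verbose, "presence matrix: %d proteins x %d fractions",
            nrow(presence), ncol(presence))
  scores <- score_all(presence, peaksets)
  log_stage(verbose, "GMPA scores: %d protein-metal pairs", nrow(scores))

  metals <- names(peaksets)
  regressions <- list()
  curves <- list()
  for (metal in metals) {
    res <- scores[scores$metal == metal, ]
    regressions[[metal]] <- fit_regression(res)
    refs <- references[[metal]]
    if (!is.null(refs)) {
      curves[[metal]] <- tryCatch(
        set_reference_curve(res, regressions[[metal]], refs,
                            min_occurrences = min_occurrences),
        gmpa_value_error = function(e) NULL)
    }
  }
  ref_curves <- Filter(Negate(is.null), curves)
  for (metal in metals) {
    if (!is.null(curves[[metal]])) next
    curves[[metal]] <- if (length(ref_curves) > 0) {
      extrapolate_curve(regressions[[metal]], ref_curves, metal = metal)
    } else {
      manual_curve(metal, regressions[[metal]][["intercept_a"]],
                   regressions[[metal]][["exponent_b"]], ratio_c = 1)
    }
  }

  significant <- list()
  reports <- list()
  covers <- list()
  summary_rows <- list()
  for (metal in metals) {
    res <- scores[scores$metal == metal, ]
    sig <- filter_significant(res, curves[[metal]],
                              min_occurrences = min_occurrences)
    significant[[metal]] <- sig
    log_stage(verbose, "%s: %d/%d proteins significant (curve source %s)",
              metal, length(sig), nrow(res), curves[[metal]]$source)
    if (length(sig) >= max(2, min_cluster_size)) {
      cl <- cluster_proteins(presence[sig, , drop = FALSE],
                             min_cluster_size = min_cluster_size,
                             deep_split = deep_split,
                             cut_height_fraction = cut_height_fraction)
      assignments <- cl$assignments
    } else {
      # too few proteins for the tree cut: the set is one cluster (or none)
      assignments <- stats::setNames(rep(1L, length(sig)), sig)
    }
    reports[[metal]] <- cluster_report(metal, presence[sig, , drop = FALSE],
                                       assignments, peaksets[[metal]])
    log_stage(verbose, "%s: %d cluster(s)", metal, reports[[metal]]$n_clusters)
    cands <- if (setcover_candidates == "significant") sig else rownames(presence)
    covers[[metal]] <- greedy_cover(
      presence, peaksets[[metal]], cands,
      scores = stats::setNames(res$score, res$protein_id))

    refs <- references[[metal]]
    observed_refs <- intersect(refs, rownames(presence))
    sig_refs <- intersect(refs, sig)
    with_known <- if (reports[[metal]]$n_clusters > 0 && length(sig_refs) > 0) {
      length(unique(assignments[sig_refs][assignments[sig_refs] > 0]))
    } else 0L
    summary_rows[[metal]] <- data.frame(
      metal = metal,
      known_subunits_total = length(refs),
      known_observed = length(observed_refs),
      known_meeting_significance = length(sig_refs),
      proteins_clustered = length(sig),
      clusters_total = reports[[metal]]$n_clusters,
      clusters_with_known = with_known,
      cover_size = covers[[metal]]$cover_size,
      n_uncovered_peaks = length(covers[[metal]]$uncovered_peaks),
      stringsAsFactors = FALSE)
  }
  summary <- do.call(rbind, summary_rows)
  rownames(summary) <- NULL
  list(presence = presence, scores = scores, curves = curves,
       significant = significant, reports = reports, covers = covers,
       summary = summary)
}

#' Run the full pipeline from input files to an output directory
#'
#' Loads and validates the experiment tables, obtains metal peaks (from
#' `peaks_file` when given — the primary, manually curated path —
#' otherwise by [detect_peaks()] for every metal in the measurement
#' table), runs [analyze_experiment()], optionally runs the InterPro-Metal
#' classifier, and writes all stage outputs as TSV:
#' `peaks_used.tsv`, `gmpa_scores.tsv`, `significance.tsv`,
#' `clusters.tsv`, `cores.tsv`, `cover.tsv`, `summary.tsv` and, with
#' annotation inputs, `ipm_predictions.tsv`. Re-running with identical
#' inputs and parameters reproduces identical files.
#'
#' @param fractions_file,metals_file,observations_file Experiment TSVs.
#' @param outdir Output directory (created if needed).
#' @param peaks_file Optional manual peak region TSV.
#' @param references_file Optional known-metalloprotein TSV
#'   (`metal`, `protein_id`).
#' @param entries_file,entries_format,matches_file,curation_file,patterns_file
#'   Optional InterPro-Metal inputs, see [ipm].
#' @param fold,window,min_len Automatic peak detection parameters (used
#'   only when `peaks_file` is absent).
#' @inheritParams analyze_experiment
#' @return The [analyze_experiment()] result list (plus `ipm` when
#'   computed), invisibly.
#' @export
run_pipeline <- function(fractions_file, metals_file, observations_file, outdir,
                         peaks_file = NULL, references_file = NULL,
                         entries_file = NULL, entries_format = "tsv",
                         matches_file = NULL, curation_file = NULL,
                         patterns_file = NULL,
                         min_peptides = 2, fold = 3.0, window = 5, min_len = 2,
                         min_occurrences = 10, min_cluster_size = 3,
                         deep_split = 2, cut_height_fraction = 0.99,
                         setcover_candidates = "significant", verbose = TRUE) {
  experiment <- load_experiment(fractions_file, metals_file, observations_file)
  log_stage(verbose, "loaded %d fractions, %d metals, %d proteins",
            nrow(experiment$fractions), length(unique(experiment$metals$metal)),
            length(unique(experiment$observations$protein_id)))
  peaksets <- if (!is.null(peaks_file)) {
    load_peak_regions(peaks_file, experiment$fractions)
  } else {
    ms <- sort(unique(experiment$metals$metal))
    stats::setNames(lapply(ms, function(m)
      detect_peaks(experiment$metals, experiment$fractions, m, fold = fold,
                   window = window, min_len = min_len)), ms)
  }
  log_stage(verbose, "peaks (%s): %s",
            if (is.null(peaks_file)) "detected" else "manual",
            paste(sprintf("%s=%d", names(peaksets),
                          vapply(peaksets, function(p) length(p$regions), 1L)),
                  collapse = " "))
  references <- if (!is.null(references_file)) load_references(references_file)
  results <- analyze_experiment(
    experiment, peaksets, references, min_peptides = min_peptides,
    min_occurrences = min_occurrences, min_cluster_size = min_cluster_size,
    deep_split = deep_split, cut_height_fraction = cut_height_fraction,
    setcover_candidates = setcover_candidates, verbose = verbose)

  if (!is.null(entries_file) && !is.null(matches_file)) {
    entries <- load_entries(entries_file, format = entries_format)
    patterns <- load_patterns(patterns_file)
    curation <- if (!is.null(curation_file)) {
      cu <- read_tsv(curation_file, required = c("entry_id", "metal", "score"))
      cu$score <- as.integer(cu$score)
      cu
    }
    matches <- read_tsv(matches_file, required = c("protein_id", "entry_id"))
    results$ipm <- predict_metal_proteins(classify_entries(entries, patterns),
                                          curation, matches)
    log_stage(verbose, "IPM: %d protein-metal predictions", nrow(results$ipm))
  }
  write_pipeline_outputs(results, peaksets, outdir)
  log_stage(verbose, "outputs written to %s", outdir)
  invisible(results)
}

write_pipeline_outputs <- function(results, peaksets, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  write_peak_regions(peaksets, file.path(outdir, "peaks_used.tsv"))
  write_tsv(results$scores, file.path(outdir, "gmpa_scores.tsv"))

  sig_df <- do.call(rbind, lapply(names(results$curves), function(metal) {
    cv <- results$curves[[metal]]
    data.frame(metal = metal, intercept_a = cv$intercept_a,
               exponent_b = cv$exponent_b, ratio_c = cv$ratio_c,
               source = cv$source,
               n_significant = length(results$significant[[metal]]),
               stringsAsFactors = FALSE)
  }))
  write_tsv(sig_df, file.path(outdir, "significance.tsv"))

  cl_df <- do.call(rbind, lapply(results$reports, function(rep) {
    if (length(rep$assignments) == 0) return(NULL)
    data.frame(metal = rep$metal, protein_id = names(rep$assignments),
               cluster_label = unname(rep$assignments), stringsAsFactors = FALSE)
  }))
  if (is.null(cl_df)) cl_df <- data.frame(metal = character(),
                                          protein_id = character(),
                                          cluster_label = integer())
  write_tsv(cl_df[order(cl_df$metal, cl_df$protein_id), ],
            file.path(outdir, "clusters.tsv"))

  core_df <- do.call(rbind, lapply(results$reports, function(rep) {
    rows <- lapply(names(rep$core_fractions), function(lab) {
      frs <- rep$core_fractions[[lab]]
      if (length(frs) == 0) return(NULL)
      data.frame(metal = rep$metal, cluster_label = as.integer(lab),
                 fraction_id = sort(frs), stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  }))
  if (is.null(core_df)) core_df <- data.frame(metal = character(),
                                              cluster_label = integer(),
                                              fraction_id = character())
  write_tsv(core_df, file.path(outdir, "cores.tsv"))

  cover_df <- do.call(rbind, lapply(results$covers, function(cv) {
    if (cv$cover_size == 0) return(NULL)
    data.frame(metal = cv$metal, rank = seq_along(cv$chosen_proteins),
               protein_id = cv$chosen_proteins,
               peaks_newly_covered = as.integer(
                 table(factor(cv$covered, levels = cv$chosen_proteins))[cv$chosen_proteins]),
               stringsAsFactors = FALSE)
  }))
  if (is.null(cover_df)) cover_df <- data.frame(metal = character(), rank = integer(),
                                                protein_id = character(),
                                                peaks_newly_covered = integer())
  write_tsv(cover_df, file.path(outdir, "cover.tsv"))
  write_tsv(results$summary, file.path(outdir, "summary.tsv"))
  if (!is.null(results$ipm)) {
    write_tsv(results$ipm, file.path(outdir, "ipm_predictions.tsv"))
  }
  invisible(outdir)
}
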