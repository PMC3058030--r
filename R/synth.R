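#' @title Synthetic fractionation experiments with planted ground truth
#' @description
#' Generates complete experiments in the package's data model so every
#' pipeline stage can be validated offline against known truth: multiple
#' separations of ordered fractions; per-metal ICP-MS-like replicate
#' traces with a noisy lognormal baseline and contiguous rectangular peak
#' regions raised `peak_fold`-fold; *planted* metalloproteins that appear
#' in their metal's peak fractions with probability `p_hit` and elsewhere
#' with probability `p_bg`; background proteins present anywhere with
#' probability `bg_presence`; and semi-quantitative peptide counts
#' (`1 + Poisson(peptide_lambda)` where present, with a configurable
#' fraction of background proteins forced to single-peptide evidence so
#' the two-peptide inclusion filter is exercised). Same-metal peak regions
#' are placed with at least a two-fraction gap so regions stay
#' individually resolvable. Deterministic for a fixed seed.
#' @name synth
NULL

#' Synthetic experiment configuration
#'
#' Defaults describe a mid-sized study: 8 separations of 60 fractions, the
#' ten default metals with 4 peaks each (2-5 fractions wide, 8-fold above
#' a lognormal baseline with 20% coefficient of variation, 2 technical
#' replicates), 5 planted metalloproteins per metal (`p_hit = 0.8`,
#' `p_bg = 0.02`) over 300 background proteins (`bg_presence = 0.03`).
#'
#' @param seed Integer RNG seed.
#' @param n_separations,fractions_per_separation Experiment geometry.
#' @param metals Character vector of metal symbols.
#' @param peaks_per_metal,peak_width_range Planted peak count per metal and
#'   inclusive width range in fractions (widths >= 2).
#' @param baseline_mean,baseline_cv,peak_fold,n_replicates ICP-MS noise
#'   model: lognormal baseline mean and coefficient of variation, in-peak
#'   fold elevation, replicate count.
#' @param planted_per_metal,p_hit,p_bg Planted metalloproteins per metal and
#'   their in-peak / off-peak presence probabilities.
#' @param n_background_proteins,bg_presence Background proteome size and
#'   uniform presence probability.
#' @param peptide_lambda Poisson rate for extra peptides where present.
#' @param frac_single_peptide Fraction of background proteins restricted to
#'   single-peptide evidence everywhere.
#' @return Validated list of class `gmpa_synth_config`.
#' @export
synth_config <- function(seed = 1, n_separations = 8, fractions_per_separation = 60,
                         metals = gmpa_metals(), peaks_per_metal = 4,
                         peak_width_range = c(2, 5), baseline_mean = 1.0,
                         baseline_cv = 0.2, peak_fold = 8.0, n_replicates = 2,
                         planted_per_metal = 5, p_hit = 0.8, p_bg = 0.02,
                         n_background_proteins = 300, bg_presence = 0.03,
                         peptide_lambda = 2.0, frac_single_peptide = 0.05) {
  cfg <- as.list(environment())
  probs <- c(p_hit = p_hit, p_bg = p_bg, bg_presence = bg_presence,
             frac_single_peptide = frac_single_peptide)
  if (any(probs < 0 | probs > 1)) {
    value_error("probabilities must lie in [0, 1]: %s",
                paste(names(probs)[probs < 0 | probs > 1], collapse = ", "))
  }
  if (peak_width_range[1] < 2) value_error("peak widths must be >= 2 fractions")
  if (peak_width_range[2] > fractions_per_separation) {
    value_error("peak width exceeds separation length")
  }
  if (baseline_mean <= 0 || peak_fold <= 0) {
    value_error("baseline_mean and peak_fold must be positive")
  }
  structure(cfg, class = "gmpa_synth_config")
}

#' Survey-scale configuration preset
#'
#' A preset sized like a full metalloproteome survey: 43 separations of 60
#' fractions (2,580 fractions), ten metals, and 50 planted plus 820
#' background proteins (870 total), for end-to-end scale testing.
#'
#' @param seed Integer RNG seed.
#' @return A `gmpa_synth_config`.
#' @export
survey_scale_config <- function(seed = 1) {
  synth_config(seed = seed, n_separations = 43, n_background_proteins = 820)
}

# place `n_peaks` regions of widths in `wr` for one metal, >= 2-fraction gap
# between same-metal regions in one separation; returns list of regions
place_regions <- function(metal, cfg) {
  occupied <- lapply(seq_len(cfg$n_separations), function(i) NULL)
  regions <- list()
  tries <- 0
  while (length(regions) < cfg$peaks_per_metal) {
    tries <- tries + 1
    if (tries > 500 * cfg$peaks_per_metal) {
      value_error("cannot place %d non-overlapping %s peaks; too many/too wide",
                  cfg$peaks_per_metal, metal)
    }
    s <- sample.int(cfg$n_separations, 1)
    w <- sample(seq(cfg$peak_width_range[1], cfg$peak_width_range[2]), 1)
    start <- sample.int(cfg$fractions_per_separation - w + 1, 1)
    iv <- c(start, start + w - 1)
    clash <- any(vapply(occupied[[s]], function(o)
      iv[1] <= o[2] + 2 && o[1] <= iv[2] + 2, TRUE))
    if (isTRUE(clash)) next
    occupied[[s]] <- c(occupied[[s]], list(iv))
    regions[[length(regions) + 1]] <- list(separation = s, start = start, width = w)
  }
  regions
}

#' Generate a synthetic experiment
#'
#' @param config A `gmpa_synth_config`.
#' @return List of class `gmpa_synth` with elements `experiment` (a
#'   validated `gmpa_experiment`), `peaksets` (metal -> `gmpa_peakset`,
#'   the planted regions, i.e. the truth a peak detector should recover),
#'   `truth` (data frame `protein_id`, `metal` of planted metalloproteins,
#'   plus `groups_per_metal`, the planted co-elution group count — 1 per
#'   metal, since a metal's planted proteins share its full peak support),
#'   and `config`.
#' @export
synth_generate <- function(config) {
  stopifnot(inherits(config, "gmpa_synth_config"))
  with_seed(config$seed, synth_generate_impl(config))
}

synth_generate_impl <- function(cfg) {
  n_sep <- cfg$n_separations
  npf <- cfg$fractions_per_separation
  sep_ids <- sprintf("S%02d", seq_len(n_sep))
  fractions <- data.frame(
    fraction_id = sprintf("%s_F%03d", rep(sep_ids, each = npf),
                          rep(seq_len(npf), n_sep)),
    separation_id = rep(sep_ids, each = npf),
    order_index = rep(seq_len(npf) - 1L, n_sep),
    parent_fraction_id = NA_character_,
    level = 2L,
    stringsAsFactors = FALSE)
  n_frac <- nrow(fractions)
  frac_of <- function(s, pos) sprintf("%s_F%03d", sep_ids[s], pos)

  # planted peak regions per metal
  peaksets <- list()
  for (metal in cfg$metals) {
    placed <- place_regions(metal, cfg)
    # canonical order so peak ids are stable
    ord <- order(vapply(placed, `[[`, 0, "separation"),
                 vapply(placed, `[[`, 0, "start"))
    regions <- lapply(seq_along(ord), function(k) {
      p <- placed[[ord[k]]]
      list(peak_id = sprintf("%s_%s_p%d", metal, sep_ids[p$separation], k),
           metal = metal, separation_id = sep_ids[p$separation],
           fraction_ids = frac_of(p$separation, seq(p$start, p$start + p$width - 1)))
    })
    peaksets[[metal]] <- new_peakset(metal, regions)
  }

  # ICP-MS traces: lognormal baseline, peak_fold inside planted regions
  sdlog <- sqrt(log(1 + cfg$baseline_cv^2))
  meanlog <- log(cfg$baseline_mean) - sdlog^2 / 2
  metal_rows <- lapply(cfg$metals, function(metal) {
    in_peak <- fractions$fraction_id %in% peaksets[[metal]]$peak_fraction_ids
    conc <- stats::rlnorm(n_frac * cfg$n_replicates, meanlog, sdlog) *
      ifelse(rep(in_peak, cfg$n_replicates), cfg$peak_fold, 1)
    data.frame(fraction_id = rep(fractions$fraction_id, cfg$n_replicates),
               metal = metal,
               replicate = rep(seq_len(cfg$n_replicates), each = n_frac),
               concentration = conc, stringsAsFactors = FALSE)
  })
  metals_df <- do.call(rbind, metal_rows)

  # planted metalloproteins then background proteome
  planted <- do.call(rbind, lapply(cfg$metals, function(metal) {
    if (cfg$planted_per_metal == 0) return(NULL)
    data.frame(protein_id = sprintf("MP_%s_%02d", metal, seq_len(cfg$planted_per_metal)),
               metal = metal, stringsAsFactors = FALSE)
  }))
  presence_rows <- list()
  for (i in seq_len(NROW(planted))) {
    in_peak <- fractions$fraction_id %in% peaksets[[planted$metal[i]]]$peak_fraction_ids
    p <- ifelse(in_peak, cfg$p_hit, cfg$p_bg)
    hit <- stats::runif(n_frac) < p
    if (any(hit)) {
      presence_rows[[length(presence_rows) + 1]] <- data.frame(
        fraction_id = fractions$fraction_id[hit],
        protein_id = planted$protein_id[i], stringsAsFactors = FALSE)
    }
  }
  bg_ids <- if (cfg$n_background_proteins > 0)
    sprintf("BG%04d", seq_len(cfg$n_background_proteins)) else character(0)
  for (id in bg_ids) {
    hit <- stats::runif(n_frac) < cfg$bg_presence
    if (any(hit)) {
      presence_rows[[length(presence_rows) + 1]] <- data.frame(
        fraction_id = fractions$fraction_id[hit], protein_id = id,
        stringsAsFactors = FALSE)
    }
  }
  obs <- do.call(rbind, presence_rows)
  if (is.null(obs)) {
    obs <- data.frame(fraction_id = character(), protein_id = character(),
                      stringsAsFactors = FALSE)
  }
  single_only <- bg_ids[stats::runif(length(bg_ids)) < cfg$frac_single_peptide]
  obs$peptide_count <- 1L + stats::rpois(nrow(obs), cfg$peptide_lambda)
  obs$peptide_count[obs$protein_id %in% single_only] <- 1L

  truth <- if (is.null(planted)) {
    data.frame(protein_id = character(), metal = character())
  } else planted
  structure(list(
    experiment = new_experiment(fractions, metals_df, obs),
    peaksets = peaksets,
    truth = truth,
    groups_per_metal = stats::setNames(rep(1L, length(cfg$metals)), cfg$metals),
    config = cfg
  ), class = "gmpa_synth")
}

#' Write a synthetic experiment to disk
#'
#' Emits exactly the interchange formats the loaders consume
#' (`fractions.tsv`, `metals.tsv`, `observations.tsv`, `peaks.tsv`), plus
#' `truth.tsv` (planted protein_id, metal) and the resolved configuration
#' as DCF text (`synth_config.dcf`).
#'
#' @param sim A `gmpa_synth` from [synth_generate()].
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_synth <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_experiment(sim$experiment, dir)
  write_peak_regions(sim$peaksets, file.path(dir, "peaks.tsv"))
  write_tsv(sim$truth[order(sim$truth$protein_id), ], file.path(dir, "truth.tsv"))
  cfg <- sim$config
  cfg$metals <- paste(cfg$metals, collapse = ",")
  cfg$peak_width_range <- paste(cfg$peak_width_range, collapse = ",")
  write.dcf(as.data.frame(unclass(cfg)), file.path(dir, "synth_config.dcf"))
  invisible(dir)
}
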