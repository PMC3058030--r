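test_that("generation is deterministic and passes full validation", {
  cfg <- synth_config(seed = 17)
  s1 <- synth_generate(cfg)
  s2 <- synth_generate(cfg)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_synth(s1, d1); write_synth(s2, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
  # the written bundle reloads through the validating loader
  exp2 <- load_experiment(file.path(d1, "fractions.tsv"),
                          file.path(d1, "metals.tsv"),
                          file.path(d1, "observations.tsv"))
  expect_s3_class(exp2, "gmpa_experiment")
  ps <- load_peak_regions(file.path(d1, "peaks.tsv"), exp2$fractions)
  expect_setequal(names(ps), cfg$metals)
  # generator does not disturb the caller's RNG stream
  set.seed(123); before <- runif(1)
  set.seed(123); invisible(synth_generate(cfg)); after <- runif(1)
  expect_identical(before, after)
})

test_that("degenerate probabilities confine planted proteins to their peaks", {
  sim <- synth_generate(synth_config(seed = 2, p_hit = 1, p_bg = 0,
                                     bg_presence = 0, n_background_proteins = 10))
  pres <- build_presence_matrix(sim$experiment$observations,
                                sim$experiment$fractions)
  res <- score_all(pres, sim$peaksets)
  for (i in seq_len(nrow(sim$truth))) {
    r <- res[res$protein_id == sim$truth$protein_id[i] &
               res$metal == sim$truth$metal[i], ]
    expect_equal(r$f_pm, r$f_p)
  }
})

test_that("planted proteins score lowest against their own metal", {
  sim <- synth_generate(synth_config(seed = 6))
  pres <- build_presence_matrix(filter_proteins(sim$experiment$observations),
                                sim$experiment$fractions)
  res <- score_all(pres, sim$peaksets)
  for (m in unique(sim$truth$metal)) {
    own_ids <- sim$truth$protein_id[sim$truth$metal == m]
    own <- mean(res$ln_score[res$protein_id %in% own_ids & res$metal == m])
    for (other in setdiff(unique(res$metal), m)) {
      expect_lt(own, mean(res$ln_score[res$protein_id %in% own_ids &
                                         res$metal == other]))
    }
  }
})

test_that("in-peak presence rate of planted proteins converges to p_hit", {
  cfg <- synth_config(seed = 31, n_separations = 20, planted_per_metal = 10,
                      peaks_per_metal = 6)
  sim <- synth_generate(cfg)
  pres <- build_presence_matrix(sim$experiment$observations,
                                sim$experiment$fractions)
  hits <- 0; trials <- 0
  for (i in seq_len(nrow(sim$truth))) {
    pid <- sim$truth$protein_id[i]
    pk <- intersect(sim$peaksets[[sim$truth$metal[i]]]$peak_fraction_ids,
                    colnames(pres))
    if (!pid %in% rownames(pres)) next
    hits <- hits + sum(pres[pid, pk])
    trials <- trials + length(pk)
  }
  se <- sqrt(cfg$p_hit * (1 - cfg$p_hit) / trials)
  expect_lt(abs(hits / trials - cfg$p_hit), 3 * se)
})

test_that("a fraction of background proteins carries only single-peptide evidence", {
  cfg <- synth_config(seed = 12, frac_single_peptide = 0.3)
  sim <- synth_generate(cfg)
  obs <- sim$experiment$observations
  bg <- grepl("^BG", obs$protein_id)
  max_pep <- tapply(obs$peptide_count[bg], obs$protein_id[bg], max)
  expect_gt(sum(max_pep == 1), 0)
  # and they are exactly the ones the inclusion filter drops
  kept <- unique(filter_proteins(obs)$protein_id)
  expect_setequal(setdiff(unique(obs$protein_id), kept), names(max_pep)[max_pep == 1])
})

test_that("the survey-scale preset is sized like a full survey", {
  cfg <- survey_scale_config(seed = 1)
  n_frac <- cfg$n_separations * cfg$fractions_per_separation
  n_prot <- cfg$n_background_proteins + cfg$planted_per_metal * length(cfg$metals)
  expect_lt(abs(n_frac - 2589) / 2589, 0.05)
  expect_lt(abs(n_prot - 870) / 870, 0.05)
})

test_that("invalid configurations are rejected", {
  expect_error(synth_config(p_hit = 1.2), class = "gmpa_value_error")
  expect_error(synth_config(peak_width_range = c(1, 4)), class = "gmpa_value_error")
  expect_error(synth_config(baseline_mean = 0), class = "gmpa_value_error")
  # infeasible placement: peaks cannot fit with the required gaps
  cfg <- synth_config(n_separations = 1, fractions_per_separation = 12,
                      peaks_per_metal = 4, peak_width_range = c(5, 5))
  expect_error(synth_generate(cfg), class = "gmpa_value_error")
})
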