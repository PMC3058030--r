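# build a GMPA-like result frame directly from (occ, ln_score) pairs
res_frame <- function(occ, ln_score, metal = "Ni",
                      ids = sprintf("P%03d", seq_along(occ))) {
  data.frame(protein_id = ids, metal = metal, f = 1000, f_m = 50,
             f_p = occ, f_pm = 0, score = exp(ln_score), ln_score = ln_score,
             stringsAsFactors = FALSE)
}

test_that("regression recovers noiseless exponential decay exactly", {
  occ <- c(5, 10, 15, 20, 40, 60)
  res <- res_frame(occ, 0.5 - 0.2 * occ)
  fit <- fit_regression(res)
  expect_equal(fit[["intercept_a"]], 0.5, tolerance = 1e-9)
  expect_equal(fit[["exponent_b"]], -0.2, tolerance = 1e-9)

  # all scores equal 1: flat fit
  res1 <- res_frame(occ, rep(0, length(occ)))
  fit1 <- fit_regression(res1)
  expect_equal(unname(fit1), c(0, 0), tolerance = 1e-12)

  expect_error(fit_regression(res[1:2, ]), class = "gmpa_value_error")
})

test_that("regression slope is negative on default synthetic data and matches lm", {
  sim <- synth_generate(synth_config(seed = 5))
  pres <- build_presence_matrix(filter_proteins(sim$experiment$observations),
                                sim$experiment$fractions)
  res <- score_all(pres, sim$peaksets)
  ni <- res[res$metal == "Ni" & res$f_p >= 1, ]
  fit <- fit_regression(ni)
  expect_lt(fit[["exponent_b"]], 0)
  ref <- stats::lm(ln_score ~ f_p, data = ni)   # independent route
  expect_equal(unname(fit), unname(coef(ref)), tolerance = 1e-8)
})

test_that("reference anchoring reproduces algebraically forced ratios", {
  reg <- c(intercept_a = 1, exponent_b = -0.3)
  # reference exactly on the regression curve: ratio 1
  res <- res_frame(c(20, 30, 12), c(1 - 0.3 * 20, -2, -3),
                   ids = c("REF1", "X1", "X2"))
  cv <- set_reference_curve(res, reg, "REF1")
  expect_equal(cv$ratio_c, 1, tolerance = 1e-12)
  expect_equal(cv$source, "reference")

  # reference at occ 20 with ln score a + 0.5*b*20: ratio 0.5
  res2 <- res_frame(c(20, 30, 12), c(1 - 0.5 * 0.3 * 20, -2, -3),
                    ids = c("REF1", "X1", "X2"))
  expect_equal(set_reference_curve(res2, reg, "REF1")$ratio_c, 0.5,
               tolerance = 1e-12)

  # references below min_occurrences are dropped (and alone, an error)
  res3 <- res_frame(c(8, 30), c(-40, -2), ids = c("RARE", "X1"))
  err <- expect_error(set_reference_curve(res3, reg, "RARE"),
                      class = "gmpa_value_error")
  expect_match(conditionMessage(err), "extrapolate_curve")
})

test_that("every qualifying reference survives the filter under its anchored curve", {
  for (seed in 1:5) {
    sim <- synth_generate(synth_config(seed = seed))
    pres <- build_presence_matrix(filter_proteins(sim$experiment$observations),
                                  sim$experiment$fractions)
    res <- score_all(pres, sim$peaksets)
    for (m in c("Fe", "Ni", "W")) {
      refs <- sim$truth$protein_id[sim$truth$metal == m]
      rm <- res[res$metal == m, ]
      cv <- set_reference_curve(rm, fit_regression(rm), refs)
      sig <- filter_significant(rm, cv)
      qualifying <- rm$protein_id[rm$protein_id %in% refs & rm$f_p >= 10]
      expect_true(all(qualifying %in% sig),
                  label = sprintf("seed %d metal %s", seed, m))
    }
  }
})

test_that("extrapolation averages reference exponent ratios", {
  reg <- c(intercept_a = 0.2, exponent_b = -0.1)
  curves <- list(manual_curve("Fe", 0, -1, 0.4), manual_curve("W", 0, -1, 0.6))
  cv <- extrapolate_curve(reg, curves, metal = "Mo")
  expect_equal(cv$ratio_c, 0.5)
  expect_equal(cv$intercept_a, 0.2)
  expect_equal(cv$exponent_b, -0.1)
  expect_equal(cv$source, "extrapolated")
  expect_equal(extrapolate_curve(reg, curves[2], "V")$ratio_c, 0.6)
  expect_error(extrapolate_curve(reg, list(), "V"), class = "gmpa_value_error")
  # with ratio < 1 and decaying scores the curve decays more slowly than
  # the regression, i.e. sits above it for positive occurrences
  occ <- seq(1, 50)
  expect_true(all(curve_value(cv, occ, log = TRUE) >
                    reg[["intercept_a"]] + reg[["exponent_b"]] * occ))
})

test_that("the significance filter honours the occurrence cutoff and inclusive boundary", {
  cv <- manual_curve("Ni", 0, -0.5, 1)
  occ <- c(9, 10, 12)
  # protein 1: tiny score but only 9 occurrences -> excluded
  # protein 2: exactly on the curve -> included
  # protein 3: just above the curve -> excluded
  res <- res_frame(occ, c(-30, -0.5 * 10, -0.5 * 12 + 0.01))
  sig <- filter_significant(res, cv, min_occurrences = 10)
  expect_identical(sig, "P002")
  # larger cutoff admits no additional proteins
  expect_true(all(filter_significant(res, cv, 12) %in% sig))
})

test_that("a steeper-than-regression curve only removes proteins", {
  # with decaying scores (b < 0), ratio >= 1 pushes the curve below the
  # regression, so it can only remove proteins relative to the regression
  # set -- the behaviour of curves anchored on strong references
  sim <- synth_generate(synth_config(seed = 9))
  pres <- build_presence_matrix(filter_proteins(sim$experiment$observations),
                                sim$experiment$fractions)
  res <- score_all(pres, sim$peaksets)
  rm <- res[res$metal == "Mo", ]
  reg <- fit_regression(rm)
  reg_curve <- manual_curve("Mo", reg[["intercept_a"]], reg[["exponent_b"]], 1)
  base <- filter_significant(rm, reg_curve)
  for (ratio in c(1, 1.5, 2)) {
    steeper <- manual_curve("Mo", reg[["intercept_a"]], reg[["exponent_b"]], ratio)
    expect_true(all(filter_significant(rm, steeper) %in% base))
  }
})
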