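flat_fractions <- function(n = 20, sep = "S1") {
  data.frame(fraction_id = sprintf("%s_F%02d", sep, seq_len(n)),
             separation_id = sep, order_index = seq_len(n) - 1L,
             parent_fraction_id = NA_character_, level = 1L,
             stringsAsFactors = FALSE)
}

trace_metals <- function(fractions, conc, metal = "Ni", n_rep = 2) {
  do.call(rbind, lapply(seq_len(n_rep), function(r) {
    data.frame(fraction_id = fractions$fraction_id, metal = metal,
               replicate = r, concentration = conc, stringsAsFactors = FALSE)
  }))
}

test_that("manual peak regions validate contiguity, size and overlap", {
  fr <- flat_fractions()
  d <- withr::local_tempdir()
  ok <- data.frame(peak_id = "p1", metal = "Ni", separation_id = "S1",
                   fraction_id = fr$fraction_id[fr$order_index %in% 4:6])
  write_tsv(ok, file.path(d, "ok.tsv"))
  ps <- load_peak_regions(file.path(d, "ok.tsv"), fr)
  expect_length(ps$Ni$regions, 1)
  expect_equal(ps$Ni$peak_fraction_ids, fr$fraction_id[fr$order_index %in% 4:6])

  gap <- ok[c(1, 3), ]  # order_index 4 and 6, 5 missing
  write_tsv(gap, file.path(d, "gap.tsv"))
  err <- expect_error(load_peak_regions(file.path(d, "gap.tsv"), fr),
                      class = "gmpa_validation_error")
  expect_match(conditionMessage(err), "5")

  single <- ok[1, ]
  write_tsv(single, file.path(d, "single.tsv"))
  expect_error(load_peak_regions(file.path(d, "single.tsv"), fr),
               class = "gmpa_validation_error")

  overlap <- rbind(ok, data.frame(peak_id = "p2", metal = "Ni",
                                  separation_id = "S1",
                                  fraction_id = fr$fraction_id[fr$order_index %in% 6:7]))
  write_tsv(overlap, file.path(d, "overlap.tsv"))
  expect_error(load_peak_regions(file.path(d, "overlap.tsv"), fr),
               class = "gmpa_validation_error")
})

test_that("detect_peaks matches the hand-evaluated local-median rule", {
  fr <- flat_fractions()

  # flat trace: nothing exceeds fold x background
  flat <- trace_metals(fr, rep(1, 20))
  expect_length(detect_peaks(flat, fr, "Ni")$regions, 0)

  # single spiked fraction: excluded by the 2-fraction minimum
  spike <- rep(1, 20); spike[9] <- 10
  expect_length(detect_peaks(trace_metals(fr, spike), fr, "Ni")$regions, 0)

  # rectangular 3-wide peak at order_index 8-10: recovered exactly
  conc <- rep(1, 20); conc[9:11] <- 10  # positions 9:11 are order_index 8:10
  ps <- detect_peaks(trace_metals(fr, conc), fr, "Ni", fold = 3, window = 5)
  expect_length(ps$regions, 1)
  expect_equal(ps$regions[[1]]$fraction_ids, fr$fraction_id[9:11])

  # a peak present in only one replicate must not be called
  ms <- trace_metals(fr, rep(1, 20))
  ms$concentration[ms$replicate == 1][9:11] <- 10
  expect_length(detect_peaks(ms, fr, "Ni")$regions, 0)

  expect_error(detect_peaks(flat, fr, "Xx"), class = "gmpa_value_error")
  expect_error(detect_peaks(flat, fr, "Ni", window = 4), class = "gmpa_value_error")
})

test_that("raising the fold threshold never adds flagged fractions", {
  set.seed(7)
  fr <- flat_fractions(40)
  conc <- exp(rnorm(40, 0, 0.2))
  conc[10:13] <- conc[10:13] * 8
  conc[25:26] <- conc[25:26] * 5
  ms <- trace_metals(fr, conc)
  prev <- NULL
  for (fold in c(2, 3, 4, 6)) {
    cur <- detect_peaks(ms, fr, "Ni", fold = fold)$peak_fraction_ids
    if (!is.null(prev)) expect_true(all(cur %in% prev))
    prev <- cur
  }
})

test_that("planted rectangular peaks over lognormal noise are recovered exactly", {
  sim <- synth_generate(synth_config(seed = 11))
  for (m in c("Ni", "Mo", "Fe")) {
    det <- detect_peaks(sim$experiment$metals, sim$experiment$fractions, m)
    truth <- lapply(sim$peaksets[[m]]$regions, function(r) sort(r$fraction_ids))
    found <- lapply(det$regions, function(r) sort(r$fraction_ids))
    expect_equal(length(found), length(truth))
    for (tr in truth) {
      expect_true(any(vapply(found, identical, TRUE, tr)))
    }
    # output satisfies the region invariants by construction of the loader
    d <- withr::local_tempdir()
    write_peak_regions(stats::setNames(list(det), m), file.path(d, "p.tsv"))
    reloaded <- load_peak_regions(file.path(d, "p.tsv"), sim$experiment$fractions)
    expect_equal(sort(reloaded[[m]]$peak_fraction_ids), sort(det$peak_fraction_ids))
  }
})

test_that("peak_fraction_count intersects regions with the analysis universe", {
  fr <- flat_fractions()
  ps <- gmpa:::new_peakset("Ni", list(
    list(peak_id = "p1", metal = "Ni", separation_id = "S1",
         fraction_ids = fr$fraction_id[1:3]),
    list(peak_id = "p2", metal = "Ni", separation_id = "S1",
         fraction_ids = fr$fraction_id[10:12])))
  expect_equal(peak_fraction_count(ps, fr$fraction_id), 6)
  expect_equal(peak_fraction_count(ps, fr$fraction_id[-1]), 5)
  empty <- gmpa:::new_peakset("Ni", list())
  expect_equal(peak_fraction_count(empty, fr$fraction_id), 0)
})
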