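test_that("experiment bundles round-trip through TSV byte-for-byte", {
  exp1 <- tiny_experiment()
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_experiment(exp1, d1)
  exp2 <- load_experiment(file.path(d1, "fractions.tsv"),
                          file.path(d1, "metals.tsv"),
                          file.path(d1, "observations.tsv"))
  write_experiment(exp2, d2)
  for (f in c("fractions.tsv", "metals.tsv", "observations.tsv")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  expect_equal(exp2$fractions, exp1$fractions, ignore_attr = TRUE)
})

test_that("loaders reject schema and integrity violations with named offenders", {
  exp1 <- tiny_experiment()
  d <- withr::local_tempdir()
  write_experiment(exp1, d)

  bad <- exp1$metals
  bad$fraction_id[1] <- "FX"
  write_tsv(bad, file.path(d, "metals_bad.tsv"))
  err <- expect_error(
    load_experiment(file.path(d, "fractions.tsv"), file.path(d, "metals_bad.tsv"),
                    file.path(d, "observations.tsv")),
    class = "gmpa_integrity_error")
  expect_match(conditionMessage(err), "FX")

  neg <- exp1$metals
  neg$concentration[2] <- -1
  write_tsv(neg, file.path(d, "metals_neg.tsv"))
  expect_error(
    load_experiment(file.path(d, "fractions.tsv"), file.path(d, "metals_neg.tsv"),
                    file.path(d, "observations.tsv")),
    class = "gmpa_value_error")

  dropped <- exp1$fractions[, setdiff(names(exp1$fractions), "order_index")]
  write_tsv(dropped, file.path(d, "fractions_bad.tsv"))
  err <- expect_error(
    load_experiment(file.path(d, "fractions_bad.tsv"), file.path(d, "metals.tsv"),
                    file.path(d, "observations.tsv")),
    class = "gmpa_schema_error")
  expect_match(conditionMessage(err), "order_index")
})

test_that("an empty observations table yields a valid zero-protein bundle", {
  exp1 <- tiny_experiment()
  d <- withr::local_tempdir()
  write_experiment(exp1, d)
  write_tsv(exp1$observations[0, ], file.path(d, "observations_empty.tsv"))
  exp2 <- load_experiment(file.path(d, "fractions.tsv"), file.path(d, "metals.tsv"),
                          file.path(d, "observations_empty.tsv"))
  expect_equal(nrow(exp2$observations), 0)
  m <- build_presence_matrix(exp2$observations, exp2$fractions)
  expect_equal(nrow(m), 0)
  expect_false(any(m))
})

test_that("parent links must form a forest", {
  exp1 <- tiny_experiment()
  fr <- exp1$fractions
  fr$parent_fraction_id[fr$fraction_id == "A01"] <- "A02"
  fr$parent_fraction_id[fr$fraction_id == "A02"] <- "A01"
  expect_error(new_experiment(fr, exp1$metals, exp1$observations),
               class = "gmpa_integrity_error")
})

test_that("the two-peptide inclusion filter is dataset-wide, idempotent and monotone", {
  obs <- data.frame(
    fraction_id = c(sprintf("A%02d", 1:10), "A01", "A02"),
    protein_id = c(rep("weak", 10), "strong", "strong"),
    peptide_count = c(rep(1L, 10), 5L, 1L), stringsAsFactors = FALSE)

  kept <- filter_proteins(obs, min_peptides = 2)
  # a protein never reaching 2 peptides disappears despite 10 sightings
  expect_false("weak" %in% kept$protein_id)
  # one confident identification retains all of the protein's rows,
  # including its 1-peptide fractions
  expect_equal(sum(kept$protein_id == "strong"), 2)
  expect_identical(filter_proteins(obs, min_peptides = 1), obs)
  expect_identical(filter_proteins(kept, min_peptides = 2), kept)

  set.seed(42)
  for (rep in 1:5) {
    robs <- data.frame(
      fraction_id = sprintf("A%02d", sample(1:10, 30, TRUE)),
      protein_id = sprintf("P%d", sample(1:8, 30, TRUE)),
      peptide_count = sample(1:6, 30, TRUE), stringsAsFactors = FALSE)
    prev <- unique(filter_proteins(robs, 1)$protein_id)
    for (mp in 2:6) {
      cur <- unique(filter_proteins(robs, mp)$protein_id)
      expect_true(all(cur %in% prev))
      prev <- cur
    }
  }
})

test_that("presence matrix has canonical ordering and one cell per observation pair", {
  exp1 <- tiny_experiment()
  m <- build_presence_matrix(exp1$observations, exp1$fractions)
  expect_identical(rownames(m), sort(unique(exp1$observations$protein_id)))
  ord <- order(exp1$fractions$separation_id, exp1$fractions$order_index)
  expect_identical(colnames(m), exp1$fractions$fraction_id[ord])
  expect_equal(sum(m), nrow(unique(exp1$observations[c("fraction_id", "protein_id")])))

  # duplicate raw rows aggregate to a single TRUE cell
  dup <- rbind(exp1$observations, exp1$observations[1, ])
  exp2 <- new_experiment(exp1$fractions, exp1$metals, dup)
  m2 <- build_presence_matrix(exp2$observations, exp2$fractions)
  expect_identical(m2, m)
})
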