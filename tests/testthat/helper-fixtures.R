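# Shared fixtures and independent oracles, all built in code.

# A tiny hand-written experiment: 2 separations x 10 fractions, 2 metals,
# 2 replicates, with an obvious Ni peak at S1 positions 4-6 and a Zn peak
# at S2 positions 2-3.
tiny_experiment <- function() {
  fractions <- data.frame(
    fraction_id = c(sprintf("A%02d", 1:10), sprintf("B%02d", 1:10)),
    separation_id = rep(c("S1", "S2"), each = 10),
    order_index = rep(0:9, 2),
    parent_fraction_id = NA_character_,
    level = 2L, stringsAsFactors = FALSE)
  conc_ni <- rep(1, 20); conc_ni[5:7] <- 10       # A05..A07
  conc_zn <- rep(1, 20); conc_zn[13:14] <- 8      # B03..B04
  metals <- rbind(
    data.frame(fraction_id = rep(fractions$fraction_id, 2), metal = "Ni",
               replicate = rep(1:2, each = 20), concentration = rep(conc_ni, 2)),
    data.frame(fraction_id = rep(fractions$fraction_id, 2), metal = "Zn",
               replicate = rep(1:2, each = 20), concentration = rep(conc_zn, 2)))
  observations <- data.frame(
    fraction_id = c("A05", "A06", "A07", "A01", "B03", "B04", "B09", "A05"),
    protein_id = c("PF01", "PF01", "PF01", "PF02", "PF03", "PF03", "PF02", "PF04"),
    peptide_count = c(3L, 2L, 4L, 2L, 5L, 2L, 3L, 2L), stringsAsFactors = FALSE)
  new_experiment(fractions, metals, observations)
}

tiny_peaks_df <- function() {
  data.frame(
    peak_id = c("ni1", "ni1", "ni1", "zn1", "zn1"),
    metal = c("Ni", "Ni", "Ni", "Zn", "Zn"),
    separation_id = c("S1", "S1", "S1", "S2", "S2"),
    fraction_id = c("A05", "A06", "A07", "B03", "B04"),
    stringsAsFactors = FALSE)
}

write_tiny_peaks <- function(dir) {
  path <- file.path(dir, "peaks.tsv")
  write_tsv(tiny_peaks_df(), path)
  path
}

# Presence matrix with k planted co-elution groups over disjoint fraction
# blocks plus sparse background noise.
make_coelution_matrix <- function(seed, k = 13, per = 6, block = 12,
                                  p_in = 0.9, p_out = 0.01, nfrac = 480) {
  set.seed(seed)
  m <- matrix(FALSE, k * per, nfrac,
              dimnames = list(sprintf("P%03d", seq_len(k * per)),
                              sprintf("F%03d", seq_len(nfrac))))
  truth <- integer(k * per)
  for (g in seq_len(k)) {
    cols <- ((g - 1) * block + 1):(g * block)
    for (j in seq_len(per)) {
      i <- (g - 1) * per + j
      m[i, ] <- stats::runif(nfrac) < p_out
      m[i, cols] <- stats::runif(block) < p_in
      truth[i] <- g
    }
  }
  list(presence = m, truth = truth)
}

# Independent hypergeometric oracle: enumerate all C(f, f_p) placements of
# the protein's fractions and count those with >= f_pm overlap with the
# first f_m "peak" fractions. Exact for small f.
enum_gmpa_oracle <- function(f, f_m, f_p, f_pm) {
  if (f_p == 0) return(if (f_pm == 0) 1 else 0)
  subsets <- utils::combn(f, f_p)
  overlap <- colSums(subsets <= f_m)
  mean(overlap >= f_pm)
}

# Exact minimum set cover by exhaustive subset search (test oracle only).
exact_cover_size <- function(inc) {
  covperable <- which(colSums(inc) > 0)
  if (length(covperable) == 0) return(0L)
  np <- nrow(inc)
  for (k in seq_len(np)) {
    for (sel in utils::combn(np, k, simplify = FALSE)) {
      if (all(colSums(inc[sel, covperable, drop = FALSE]) > 0)) return(k)
    }
  }
  np
}

# Random peak-cover incidence instance for set-cover tests.
random_cover_instance <- function(seed, max_prot = 12, max_peaks = 8) {
  set.seed(seed)
  np <- sample(2:max_prot, 1)
  nk <- sample(2:max_peaks, 1)
  inc <- matrix(stats::runif(np * nk) < 0.35, np, nk,
                dimnames = list(sprintf("P%02d", seq_len(np)),
                                sprintf("K%02d", seq_len(nk))))
  inc
}

# Build a gmpa_peakset + presence matrix realizing a given incidence matrix:
# peak j occupies its own pair of fraction columns; protein i is present in
# the first fraction of peak j iff inc[i, j].
cover_fixture_from_incidence <- function(inc) {
  np <- nrow(inc); nk <- ncol(inc)
  frac_ids <- sprintf("F%03d", seq_len(2 * nk + 2))
  fractions <- data.frame(fraction_id = frac_ids, separation_id = "S1",
                          order_index = seq_along(frac_ids) - 1L,
                          parent_fraction_id = NA_character_, level = 1L)
  regions <- lapply(seq_len(nk), function(j) {
    list(peak_id = colnames(inc)[j], metal = "Ni", separation_id = "S1",
         fraction_ids = frac_ids[c(2 * j - 1, 2 * j)])
  })
  peakset <- gmpa:::new_peakset("Ni", regions)
  presence <- matrix(FALSE, np, length(frac_ids),
                     dimnames = list(rownames(inc), frac_ids))
  for (j in seq_len(nk)) presence[inc[, j], 2 * j - 1] <- TRUE
  list(peakset = peakset, presence = presence)
}

# Small but complete pipeline scenario reused by determinism tests.
small_pipeline_config <- function() {
  synth_config(seed = 42, n_separations = 3, fractions_per_separation = 40,
               metals = c("Mo", "Ni", "Zn"), peaks_per_metal = 2,
               planted_per_metal = 3, n_background_proteins = 40)
}

run_small_pipeline <- function(outdir, indir) {
  sim <- synth_generate(small_pipeline_config())
  write_synth(sim, indir)
  refs <- data.frame(metal = sim$truth$metal, protein_id = sim$truth$protein_id)
  write_tsv(refs, file.path(indir, "references.tsv"))
  run_pipeline(file.path(indir, "fractions.tsv"), file.path(indir, "metals.tsv"),
               file.path(indir, "observations.tsv"), outdir,
               peaks_file = file.path(indir, "peaks.tsv"),
               references_file = file.path(indir, "references.tsv"),
               min_occurrences = 5, verbose = FALSE)
}

# Small XML/TSV InterPro entry fixtures sharing the same content.
ipm_entries_df <- function() {
  data.frame(
    entry_id = c("IPR000001", "IPR000002", "IPR000003", "IPR000004"),
    name = c("Molybdopterin oxidoreductase", "Zinc finger, C2H2 type",
             "Iron-sulfur cluster with zinc finger accessory domain",
             "Kinase of unknown specificity"),
    abstract = c("Catalyses transfer using a molybdopterin cofactor.",
                 "Classical C2H2 zinc finger fold.",
                 "Contains a [4Fe-4S] iron-sulfur cluster and a zinc finger.",
                 "No metal terms appear here."),
    stringsAsFactors = FALSE)
}

write_ipm_xml <- function(path) {
  df <- ipm_entries_df()
  entries <- paste0(sprintf(
    "  <interpro id=\"%s\">\n    <name>%s</name>\n    <abstract>%s</abstract>\n  </interpro>",
    df$entry_id, df$name, df$abstract), collapse = "\n")
  writeLines(c("<interprodb>", entries, "</interprodb>"), path)
  path
}
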