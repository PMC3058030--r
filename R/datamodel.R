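#' @title Experiment data model: fractions, metal measurements, protein observations
#' @description
#' A fractionation experiment is represented as three plain data frames
#' bundled in a `gmpa_experiment` list:
#'
#' * `fractions` — one row per chromatographic fraction: `fraction_id`
#'   (opaque unique string), `separation_id` (one chromatographic run),
#'   `order_index` (0-based elution order within the separation, unique per
#'   separation), optional `parent_fraction_id` (source fraction in the
#'   multi-level purification hierarchy; links must form a forest) and
#'   `level` (column level, e.g. 2 for a second-level separation).
#' * `metals` — ICP-MS concentrations: `fraction_id`, `metal`, `replicate`
#'   (integer >= 1), `concentration` (non-negative, instrument units such as
#'   ppb). `(fraction_id, metal, replicate)` is unique.
#' * `observations` — MS/MS protein identifications: `fraction_id`,
#'   `protein_id` (ORF identifier, e.g. "PF1587"), `peptide_count`
#'   (integer >= 1). `(fraction_id, protein_id)` is unique after aggregation.
#'
#' Elution order is carried explicitly by `order_index`; no meaning is ever
#' attached to the lexicographic order of fraction IDs.
#' @name datamodel
NULL

FRACTION_COLS <- c("fraction_id", "separation_id", "order_index",
                   "parent_fraction_id", "level")
METAL_COLS <- c("fraction_id", "metal", "replicate", "concentration")
OBS_COLS <- c("fraction_id", "protein_id", "peptide_count")

validate_fractions <- function(fractions) {
  f <- fractions
  if (anyDuplicated(f$fraction_id)) {
    dups <- unique(f$fraction_id[duplicated(f$fraction_id)])
    integrity_error("duplicate fraction_id(s): %s",
                    paste(utils::head(dups, 5), collapse = ", "))
  }
  key <- paste(f$separation_id, f$order_index)
  if (anyDuplicated(key)) {
    integrity_error("order_index not unique within separation: %s",
                    paste(utils::head(unique(key[duplicated(key)]), 5), collapse = "; "))
  }
  if (any(f$order_index < 0)) value_error("order_index must be >= 0")
  if (any(f$level < 1)) value_error("level must be >= 1")
  parent <- f$parent_fraction_id
  has_parent <- !is.na(parent)
  if (any(has_parent)) {
    unknown <- setdiff(parent[has_parent], f$fraction_id)
    if (length(unknown) > 0) {
      integrity_error("parent_fraction_id(s) not in table: %s",
                      paste(utils::head(unknown, 5), collapse = ", "))
    }
    # forest check: follow parent links; a cycle revisits a node
    idx <- match(parent, f$fraction_id)
    for (start in which(has_parent)) {
      seen <- integer(0)
      i <- start
      while (!is.na(i)) {
        if (i %in% seen) integrity_error(
          "parent links contain a cycle through fraction %s", f$fraction_id[start])
        seen <- c(seen, i)
        i <- idx[i]
      }
    }
  }
  invisible(f)
}

validate_metals <- function(metals, fractions) {
  m <- metals
  if (any(m$concentration < 0)) {
    bad <- utils::head(m$fraction_id[m$concentration < 0], 5)
    value_error("negative concentration(s) at fraction(s): %s",
                paste(bad, collapse = ", "))
  }
  if (any(m$replicate < 1)) value_error("replicate must be >= 1")
  key <- paste(m$fraction_id, m$metal, m$replicate)
  if (anyDuplicated(key)) {
    integrity_error("duplicate (fraction_id, metal, replicate): %s",
                    paste(utils::head(unique(key[duplicated(key)]), 5), collapse = "; "))
  }
  dangling <- setdiff(unique(m$fraction_id), fractions$fraction_id)
  if (length(dangling) > 0) {
    integrity_error("metal measurements reference unknown fraction(s): %s",
                    paste(utils::head(dangling, 10), collapse = ", "))
  }
  invisible(m)
}

validate_observations <- function(observations, fractions) {
  o <- observations
  if (nrow(o) > 0 && any(o$peptide_count < 1)) value_error("peptide_count must be >= 1")
  dangling <- setdiff(unique(o$fraction_id), fractions$fraction_id)
  if (length(dangling) > 0) {
    integrity_error("observations reference unknown fraction(s): %s",
                    paste(utils::head(dangling, 10), collapse = ", "))
  }
  invisible(o)
}

# Aggregate duplicate (fraction, protein) rows by summing peptide counts.
aggregate_observations <- function(observations) {
  if (nrow(observations) == 0) return(observations)
  key <- paste(observations$fraction_id, observations$protein_id, sep = "\r")
  if (!anyDuplicated(key)) return(observations)
  agg <- rowsum(observations$peptide_count, key, reorder = FALSE)
  parts <- strsplit(rownames(agg), "\r", fixed = TRUE)
  data.frame(fraction_id = vapply(parts, `[`, "", 1L),
             protein_id = vapply(parts, `[`, "", 2L),
             peptide_count = as.integer(agg[, 1L]),
             stringsAsFactors = FALSE)
}

#' Load a fractionation experiment from its three TSV tables
#'
#' Reads the fraction table, the ICP-MS metal concentration table and the
#' MS/MS protein observation table, validates all data-model invariants
#' (unique identifiers, elution-order uniqueness per separation, acyclic
#' parent links, non-negative concentrations, no dangling fraction
#' references) and aggregates duplicate observation rows by summing their
#' peptide counts.
#'
#' @param fractions_file,metals_file,observations_file Paths to TSV files
#'   with columns as described in [datamodel].
#' @return A list of class `gmpa_experiment` with elements `fractions`,
#'   `metals`, `observations`.
#' @seealso [write_experiment()], [filter_proteins()], [build_presence_matrix()]
#' @export
load_experiment <- function(fractions_file, metals_file, observations_file) {
  fractions <- read_tsv(fractions_file, required = FRACTION_COLS)
  metals <- read_tsv(metals_file, required = METAL_COLS)
  observations <- read_tsv(observations_file, required = OBS_COLS)
  fractions$fraction_id <- as.character(fractions$fraction_id)
  fractions$separation_id <- as.character(fractions$separation_id)
  fractions$order_index <- as.integer(fractions$order_index)
  fractions$parent_fraction_id <- as.character(fractions$parent_fraction_id)
  fractions$level <- as.integer(fractions$level)
  metals$fraction_id <- as.character(metals$fraction_id)
  metals$metal <- as.character(metals$metal)
  metals$replicate <- as.integer(metals$replicate)
  metals$concentration <- as.numeric(metals$concentration)
  observations$fraction_id <- as.character(observations$fraction_id)
  observations$protein_id <- as.character(observations$protein_id)
  observations$peptide_count <- as.integer(observations$peptide_count)
  new_experiment(fractions, metals, observations)
}

#' Construct an experiment bundle from in-memory tables
#'
#' Same validation path as [load_experiment()], for data frames already in
#' memory (e.g. produced by [synth_generate()]).
#'
#' @param fractions,metals,observations Data frames as described in [datamodel].
#' @return A validated `gmpa_experiment` list.
#' @export
new_experiment <- function(fractions, metals, observations) {
  validate_fractions(fractions)
  validate_metals(metals, fractions)
  observations <- aggregate_observations(observations)
  validate_observations(observations, fractions)
  structure(list(fractions = fractions[FRACTION_COLS],
                 metals = metals[METAL_COLS],
                 observations = observations[OBS_COLS]),
            class = "gmpa_experiment")
}

#' @export
print.gmpa_experiment <- function(x, ...) {
  cat(sprintf("gmpa experiment: %d fractions (%d separations), %d metals, %d proteins\n",
              nrow(x$fractions), length(unique(x$fractions$separation_id)),
              length(unique(x$metals$metal)),
              length(unique(x$observations$protein_id))))
  invisible(x)
}

#' Write an experiment bundle to canonical TSV files
#'
#' Rows are written in canonical order (fractions by separation and elution
#' order; measurements and observations by fraction, then metal/protein) so
#' that a load/write cycle is byte-stable.
#'
#' @param experiment A `gmpa_experiment`.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the three file paths, invisibly.
#' @export
write_experiment <- function(experiment, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fr <- experiment$fractions
  fr <- fr[order(fr$separation_id, fr$order_index), ]
  me <- experiment$metals
  me <- me[order(me$fraction_id, me$metal, me$replicate), ]
  ob <- experiment$observations
  ob <- ob[order(ob$fraction_id, ob$protein_id), ]
  paths <- c(fractions = file.path(dir, "fractions.tsv"),
             metals = file.path(dir, "metals.tsv"),
             observations = file.path(dir, "observations.tsv"))
  write_tsv(fr, paths[["fractions"]])
  write_tsv(me, paths[["metals"]])
  write_tsv(ob, paths[["observations"]])
  invisible(paths)
}

#' Filter proteins by dataset-wide peptide support
#'
#' Retains exactly the proteins whose maximum per-fraction peptide count
#' anywhere in the dataset reaches `min_peptides` (default 2, the usual
#' two-peptide identification rule). A protein identified confidently once
#' is trusted in all its fractions, so per-fraction rows of retained
#' proteins — including single-peptide fractions — are kept unchanged.
#' Idempotent, and monotone in `min_peptides`.
#'
#' @param observations Observation data frame (`fraction_id`, `protein_id`,
#'   `peptide_count`).
#' @param min_peptides Minimum peptide count a protein must reach in at
#'   least one fraction; must be >= 1. With 1, the input is returned as is.
#' @return The filtered observation data frame.
#' @export
filter_proteins <- function(observations, min_peptides = 2) {
  if (min_peptides < 1) value_error("min_peptides must be >= 1")
  if (min_peptides == 1 || nrow(observations) == 0) return(observations)
  max_per_protein <- tapply(observations$peptide_count, observations$protein_id, max)
  keep <- names(max_per_protein)[max_per_protein >= min_peptides]
  observations[observations$protein_id %in% keep, , drop = FALSE]
}

#' Build the Boolean protein presence matrix
#'
#' Reduces semi-quantitative peptide counts to presence/absence: cell
#' `[protein, fraction]` is `TRUE` iff at least one observation with
#' `peptide_count >= 1` exists for that pair. Columns are all fractions in
#' `fractions`, ordered by `(separation_id, order_index)`; rows are the
#' observed proteins in lexicographic order. This fixed canonical ordering
#' makes every downstream computation independent of input row order.
#'
#' @param observations Observation data frame (typically after
#'   [filter_proteins()]).
#' @param fractions Fraction table defining the analysis universe.
#' @return Logical matrix, proteins x fractions, with dimnames.
#' @export
build_presence_matrix <- function(observations, fractions) {
  dangling <- setdiff(unique(observations$fraction_id), fractions$fraction_id)
  if (length(dangling) > 0) {
    integrity_error("observations reference unknown fraction(s): %s",
                    paste(utils::head(dangling, 10), collapse = ", "))
  }
  ord <- order(fractions$separation_id, fractions$order_index)
  frac_ids <- fractions$fraction_id[ord]
  prot_ids <- sort(unique(observations$protein_id))
  m <- matrix(FALSE, nrow = length(prot_ids), ncol = length(frac_ids),
              dimnames = list(prot_ids, frac_ids))
  if (nrow(observations) > 0) {
    m[cbind(match(observations$protein_id, prot_ids),
            match(observations$fraction_id, frac_ids))] <- TRUE
  }
  m
}
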