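#' @title InterPro-Metal (IPM) keyword classification
#' @description
#' Bioinformatic metalloprotein prediction from domain annotations: a set
#' of case-insensitive regular-expression patterns describing metal ions,
#' metal cofactors and metal-binding domains is matched against the name
#' and abstract of each InterPro entry, attaching candidate metals to
#' entries. Manually assigned curation scores veto spurious keyword hits
#' (score 0 excludes an entry/metal pair; any positive score keeps it; an
#' uncurated pair is kept by default). Joining the entry/metal table with a
#' proteome's protein-to-entry matches yields per-protein metal
#' predictions. The shipped pattern file
#' (`system.file("extdata", "ipm_patterns.tsv", package = "gmpa")`) covers
#' the ten default metals and is plain data the user can replace.
#' @name ipm
NULL

#' Load InterPro entry descriptions
#'
#' Accepts either the InterPro XML dialect (elements `<interpro id=...>`
#' with `<name>` and `<abstract>` children; only id, name and abstract are
#' extracted) or a simplified TSV (`entry_id`, `name`, `abstract`; free
#' text quoted). Whitespace in abstracts is normalized to single spaces.
#'
#' @param source File path.
#' @param format `"interpro_xml"` or `"tsv"`.
#' @return Data frame `entry_id`, `name`, `abstract`.
#' @export
load_entries <- function(source, format = c("tsv", "interpro_xml")) {
  format <- match.arg(format)
  if (format == "tsv") {
    df <- read_tsv(source, required = c("entry_id", "name", "abstract"),
                   quote = "\"")
    df$entry_id <- as.character(df$entry_id)
    df$name <- as.character(df$name)
    df$abstract <- as.character(df$abstract)
    df$abstract[is.na(df$abstract)] <- ""
  } else {
    doc <- tryCatch(xml2::read_xml(source), error = function(e)
      schema_error("malformed InterPro XML in %s: %s", source, conditionMessage(e)))
    nodes <- xml2::xml_find_all(doc, "//interpro")
    df <- data.frame(
      entry_id = xml2::xml_attr(nodes, "id"),
      name = vapply(nodes, function(n)
        xml2::xml_text(xml2::xml_find_first(n, "./name")), ""),
      abstract = vapply(nodes, function(n) {
        a <- xml2::xml_find_first(n, "./abstract")
        if (inherits(a, "xml_missing")) "" else xml2::xml_text(a)
      }, ""),
      stringsAsFactors = FALSE)
  }
  df$abstract <- gsub("\\s+", " ", trimws(df$abstract))
  if (anyDuplicated(df$entry_id)) {
    integrity_error("duplicate entry_id(s): %s",
                    paste(unique(df$entry_id[duplicated(df$entry_id)]), collapse = ", "))
  }
  df
}

#' Write entries to the simplified TSV dialect
#'
#' @param entries Entry data frame from [load_entries()].
#' @param path Output path. Free-text fields are quoted so embedded tabs
#'   round-trip.
#' @return `path`, invisibly.
#' @export
write_entries <- function(entries, path) {
  write_tsv(entries[c("entry_id", "name", "abstract")], path, quote = TRUE)
}

#' Load metal keyword patterns
#'
#' @param path TSV with columns `metal`, `pattern`, `note`; defaults to the
#'   pattern file shipped with the package. Every pattern must compile as a
#'   Perl-compatible regular expression.
#' @return Data frame `metal`, `pattern`, `note`.
#' @export
load_patterns <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "ipm_patterns.tsv", package = "gmpa")
  }
  df <- read_tsv(path, required = c("metal", "pattern", "note"))
  df$metal <- as.character(df$metal)
  df$pattern <- as.character(df$pattern)
  for (p in df$pattern) {
    ok <- tryCatch({ grepl(p, "", perl = TRUE); TRUE }, error = function(e) FALSE)
    if (!ok) value_error("pattern does not compile: %s", p)
  }
  df
}

#' Classify InterPro entries by metal keywords
#'
#' Metal `m` is attached to an entry iff any of `m`'s patterns matches the
#' entry name or abstract, case-insensitively. Idempotent; adding patterns
#' can only add classifications.
#'
#' @param entries Entry data frame from [load_entries()].
#' @param patterns Pattern data frame from [load_patterns()].
#' @return Data frame `entry_id`, `metal`, one row per classified pair,
#'   sorted; zero rows when nothing matches.
#' @export
classify_entries <- function(entries, patterns) {
  text <- paste(entries$name, entries$abstract)
  rows <- lapply(sort(unique(patterns$metal)), function(metal) {
    hit <- rep(FALSE, nrow(entries))
    for (p in patterns$pattern[patterns$metal == metal]) {
      hit <- hit | grepl(p, text, ignore.case = TRUE, perl = TRUE)
    }
    if (!any(hit)) return(NULL)
    data.frame(entry_id = entries$entry_id[hit], metal = metal,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(entry_id = character(), metal = character(),
                      stringsAsFactors = FALSE)
  }
  out <- out[order(out$entry_id, out$metal), ]
  rownames(out) <- NULL
  out
}

#' Predict metal-associated proteins from domain matches
#'
#' Joins the entry/metal classification with a protein-to-entry match
#' table. A (protein, metal) pair is predicted iff the protein matches at
#' least one entry carrying that metal whose curation either does not
#' exist or has a positive score; curation score 0 marks a spurious
#' keyword hit and vetoes that entry/metal pair. Positive curation scores
#' never add predictions beyond the pattern matches.
#'
#' @param entry_metals Data frame `entry_id`, `metal` from
#'   [classify_entries()].
#' @param curation Optional data frame `entry_id`, `metal`, `score`
#'   (integer >= 0); `NULL` means no curation.
#' @param matches Data frame `protein_id`, `entry_id`.
#' @return Data frame `protein_id`, `metal`, `supporting_entries`
#'   (comma-joined entry IDs), sorted; the `predictions.tsv` format.
#' @export
predict_metal_proteins <- function(entry_metals, curation = NULL, matches) {
  em <- entry_metals
  if (!is.null(curation) && nrow(curation) > 0) {
    if (any(curation$score < 0)) value_error("curation scores must be >= 0")
    vetoed <- paste(curation$entry_id, curation$metal)[curation$score == 0]
    em <- em[!(paste(em$entry_id, em$metal) %in% vetoed), , drop = FALSE]
  }
  joined <- merge(matches, em, by = "entry_id")
  if (nrow(joined) == 0) {
    return(data.frame(protein_id = character(), metal = character(),
                      supporting_entries = character(), stringsAsFactors = FALSE))
  }
  key <- paste(joined$protein_id, joined$metal, sep = "\r")
  supp <- tapply(joined$entry_id, key,
                 function(e) paste(sort(unique(e)), collapse = ","))
  parts <- strsplit(names(supp), "\r", fixed = TRUE)
  out <- data.frame(protein_id = vapply(parts, `[`, "", 1L),
                    metal = vapply(parts, `[`, "", 2L),
                    supporting_entries = unname(unlist(supp)),
                    stringsAsFactors = FALSE)
  out <- out[order(out$protein_id, out$metal), ]
  rownames(out) <- NULL
  out
}
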