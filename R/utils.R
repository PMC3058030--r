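#' Metal symbols tracked by default
#'
#' The ten metals routinely profiled in native fractionation metalloproteomics
#' of *Pyrococcus furiosus*-style experiments. The set is a default, not a
#' restriction: any character symbol is accepted wherever a `metal` argument
#' appears, as long as it is used consistently across tables.
#'
#' @return Character vector of metal symbols.
#' @export
#' @examples
#' gmpa_metals()
gmpa_metals <- function() {
  c("Co", "Fe", "Mn", "Mo", "Ni", "Pb", "U", "V", "W", "Zn")
}

# sprintf-style stop/warning without call noise
stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# condition constructors so callers can distinguish error classes
gmpa_error <- function(class, fmt, ...) {
  stop(structure(
    class = c(class, "gmpa_error", "error", "condition"),
    list(message = sprintf(fmt, ...), call = NULL)
  ))
}
schema_error <- function(fmt, ...) gmpa_error("gmpa_schema_error", fmt, ...)
integrity_error <- function(fmt, ...) gmpa_error("gmpa_integrity_error", fmt, ...)
value_error <- function(fmt, ...) gmpa_error("gmpa_value_error", fmt, ...)
validation_error <- function(fmt, ...) gmpa_error("gmpa_validation_error", fmt, ...)

#' Read a tab-separated table
#'
#' UTF-8 TSV with one header row; "." denotes a missing optional field.
#' Used for every tabular interchange format in the package.
#'
#' @param path File path.
#' @param required Character vector of column names that must be present.
#' @param quote Quote character passed to [utils::read.delim()] (entry
#'   abstracts may contain quoted embedded tabs; plain tables use none).
#' @return A `data.frame` with character columns left unconverted.
#' @export
read_tsv <- function(path, required = character(), quote = "") {
  if (!file.exists(path)) schema_error("input file not found: %s", path)
  df <- utils::read.delim(path, sep = "\t", header = TRUE, quote = quote,
                          na.strings = ".", stringsAsFactors = FALSE,
                          check.names = FALSE, fileEncoding = "UTF-8")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    schema_error("%s: missing required column(s): %s", path,
                 paste(missing_cols, collapse = ", "))
  }
  df
}

#' Write a tab-separated table
#'
#' Canonical writer matching [read_tsv()]: UTF-8, tab separators, one header
#' row, `NA` written as ".". Character fields are quoted only when `quote`
#' is `TRUE` (needed for free-text columns such as InterPro abstracts).
#'
#' @param df Data frame to write.
#' @param path Output path.
#' @param quote Quote character fields?
#' @return `path`, invisibly.
#' @export
write_tsv <- function(df, path, quote = FALSE) {
  utils::write.table(df, path, sep = "\t", quote = quote, na = ".",
                     row.names = FALSE, col.names = TRUE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

# Evaluate an expression with a private RNG stream seeded by `seed`,
# restoring the caller's .Random.seed afterwards.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
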