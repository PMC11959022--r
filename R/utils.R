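# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Normalize a MedDRA term string
#'
#' Collapses internal whitespace and trims; used before any PT comparison.
#' Lookup keys are additionally case-folded by the caller.
#'
#' @param x character vector of terms.
#' @return character vector, whitespace-normalized.
#' @keywords internal
normalize_term <- function(x) {
  x <- gsub("[[:space:]]+", " ", x)
  trimws(x)
}

# Drug-name normalization for keyword matching: case-fold, map runs of
# hyphens/whitespace to a single space ("DCC-2618" and "DCC 2618" coincide).
normalize_drugname <- function(x) {
  x <- tolower(x)
  x <- gsub("[-[:space:]]+", " ", x)
  trimws(x)
}

# FAERS date fields are digit strings: 8 (day), 6 (month) or 4 (year)
# precision. Anything else counts as missing.
date_precision <- function(x) {
  out <- integer(length(x))
  ok <- !is.na(x) & grepl("^[0-9]+$", x)
  n <- nchar(x)
  out[ok & n == 8L] <- 8L
  out[ok & n == 6L] <- 6L
  out[ok & n == 4L] <- 4L
  out
}

# Day difference event - start for full-precision (8-digit) date strings.
days_between <- function(start8, event8) {
  as.integer(as.Date(event8, format = "%Y%m%d") -
             as.Date(start8, format = "%Y%m%d"))
}

# Deterministic write of a data.frame as TSV (used for all report tables).
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, na = "")
  invisible(path)
}

# Open a text connection, transparently handling .gz suffixes.
open_text <- function(path) {
  if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
}

stop_field <- function(field, msg) {
  stop(sprintf("invalid config field '%s': %s", field, msg), call. = FALSE)
}

# Evaluate an expression with a temporarily fixed RNG seed, restoring the
# caller's RNG state afterwards so generation never perturbs a session.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
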