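#' Read a FAERS quarterly ASCII table
#'
#' FAERS quarterly extracts are "$"-delimited text files with a single
#' header line naming the fields; empty strings are missing values. Plain
#' and gzip-compressed files are accepted. Rows whose field count does not
#' match the header (ragged rows) are skipped and counted in the
#' `n_ragged` attribute rather than aborting the load.
#'
#' @param path path to the table file (optionally `.gz`).
#' @param table_kind optional label, one of DEMO, DRUG, REAC, OUTC, RPSR,
#'   THER, INDI; recorded on the result.
#' @return a character data.frame, one row per well-formed data line, with
#'   attributes `n_ragged` (skipped row count) and `table_kind`.
#' @export
read_faers_table <- function(path, table_kind = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  con <- open_text(path)
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE, encoding = "latin1")
  if (length(lines) == 0) stop("empty file (no header): ", path, call. = FALSE)
  header <- strsplit(lines[1], "$", fixed = TRUE)[[1]]
  header <- tolower(trimws(header))
  if (!"primaryid" %in% header)
    stop("missing PRIMARYID column in ", path, call. = FALSE)
  body <- lines[-1]
  body <- body[nzchar(body)]
  parts <- strsplit(body, "$", fixed = TRUE)
  # a trailing empty field is dropped by strsplit; pad those rows back
  nf <- lengths(parts)
  trail <- nf == length(header) - 1L & endsWith(body, "$")
  parts[trail] <- lapply(parts[trail], function(p) c(p, ""))
  nf <- lengths(parts)
  ok <- nf == length(header)
  n_ragged <- sum(!ok)
  parts <- parts[ok]
  if (length(parts)) {
    m <- matrix(unlist(parts), ncol = length(header), byrow = TRUE)
    df <- as.data.frame(m, stringsAsFactors = FALSE)
  } else {
    df <- as.data.frame(matrix(character(0), ncol = length(header)),
                        stringsAsFactors = FALSE)
  }
  names(df) <- header
  bad_pid <- !nzchar(df$primaryid)
  n_ragged <- n_ragged + sum(bad_pid)
  df <- df[!bad_pid, , drop = FALSE]
  rownames(df) <- NULL
  attr(df, "n_ragged") <- n_ragged
  attr(df, "table_kind") <- table_kind
  df
}

#' Read a deleted-case list
#'
#' One CASEID per line; blank lines ignored.
#'
#' @param path path to the list (optionally `.gz`).
#' @return character vector of CASEIDs.
#' @export
read_deleted_cases <- function(path) {
  con <- open_text(path)
  on.exit(close(con))
  x <- trimws(readLines(con, warn = FALSE))
  x[nzchar(x)]
}

#' Deduplicate DEMO case versions and drop deleted cases
#'
#' FAERS distributes every revision of a case; analysis keeps one row per
#' CASEID. Following FDA-recommended practice, the version with the latest
#' FDA date is retained, ties broken by the largest numeric PRIMARYID;
#' cases on the deleted list are then removed. FDA dates compare
#' lexicographically on the zero-padded digit string, which is valid for
#' YYYYMMDD prefixes (8-, 6- or 4-digit). Output is sorted by CASEID so
#' repeated runs are byte-stable.
#'
#' @param demo DEMO rows from [read_faers_table()]; must carry `caseid` and
#'   `fda_dt` columns.
#' @param deleted_caseids character vector of CASEIDs to drop.
#' @return the deduplicated DEMO data.frame (a subset of the input rows).
#' @export
dedupe_demo <- function(demo, deleted_caseids = character()) {
  if (nrow(demo) == 0) return(demo)
  if (!all(c("caseid", "fda_dt") %in% names(demo)))
    stop("DEMO table must have caseid and fda_dt columns", call. = FALSE)
  pid_num <- suppressWarnings(as.numeric(demo$primaryid))
  pid_num[is.na(pid_num)] <- -Inf
  ord <- order(demo$caseid, demo$fda_dt, pid_num, method = "radix",
               decreasing = c(FALSE, TRUE, TRUE))
  keep <- ord[!duplicated(demo$caseid[ord])]
  out <- demo[sort(keep), , drop = FALSE]
  out <- out[!(out$caseid %in% deleted_caseids), , drop = FALSE]
  out <- out[order(out$caseid, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Age normalization factors to years; unknown units -> NA.
AGE_FACTORS <- c(YR = 1, DEC = 10, MON = 1 / 12, WK = 1 / 52.18,
                 DY = 1 / 365.25)
WEIGHT_MAX_KG <- 400  # crude outlier guard; heavier values set missing

parse_age_years <- function(age, age_cod) {
  v <- suppressWarnings(as.numeric(age))
  f <- AGE_FACTORS[toupper(trimws(age_cod))]
  f[is.na(f) & nzchar(trimws(age_cod)) == FALSE] <- 1  # blank unit: assume years
  out <- v * unname(f)
  out[!is.finite(out) | out < 0] <- NA_real_
  out
}

parse_weight_kg <- function(wt) {
  v <- suppressWarnings(as.numeric(wt))
  v[!is.finite(v) | v <= 0 | v > WEIGHT_MAX_KG] <- NA_real_
  v
}

OUTCOME_CODES <- c("DE", "LT", "HO", "DS", "CA", "RI", "OT")

#' Assemble linked case reports from the per-table rows
#'
#' Joins DRUG/REAC/OUTC/THER rows onto the deduplicated DEMO rows by
#' PRIMARYID. Child rows whose PRIMARYID is absent from DEMO (orphans,
#' e.g. rows belonging to superseded case versions) are dropped and
#' tallied, never fatal. Age is normalized to years (decades, months,
#' weeks, days by fixed factors), weight to kilograms with values over
#' 400 kg set missing, and reaction PTs whitespace-normalized.
#'
#' @param demo deduplicated DEMO rows ([dedupe_demo()]).
#' @param drug,reac,outc,ther the corresponding child tables (any may be
#'   an empty data.frame).
#' @return a `faers_cases` object: list of data.frames `demo` (one row per
#'   case, with parsed `age_years`, `weight_kg`, `sex`, `occupation`,
#'   `country`, `event_dt`, `fda_dt`), `drugs`, `reactions`, `outcomes`,
#'   `therapies`, and an `anomalies` list of tallies.
#' @export
link_cases <- function(demo, drug, reac, outc, ther) {
  pid <- demo$primaryid
  take <- function(child, cols) {
    if (is.null(child) || nrow(child) == 0) {
      out <- as.data.frame(matrix(character(0), ncol = length(cols)),
                           stringsAsFactors = FALSE)
      names(out) <- cols
      return(list(df = out, orphans = 0L))
    }
    missing_cols <- setdiff(cols, names(child))
    for (mc in missing_cols) child[[mc]] <- ""
    keep <- child$primaryid %in% pid
    list(df = child[keep, cols, drop = FALSE], orphans = sum(!keep))
  }
  d <- take(drug, c("primaryid", "drug_seq", "role_cod", "drugname", "prod_ai"))
  r <- take(reac, c("primaryid", "pt"))
  o <- take(outc, c("primaryid", "outc_cod"))
  t <- take(ther, c("primaryid", "dsg_drug_seq", "start_dt"))

  r$df$pt <- normalize_term(r$df$pt)
  bad_pt <- !nzchar(r$df$pt)
  r$df <- r$df[!bad_pt, , drop = FALSE]

  o$df$outc_cod <- toupper(trimws(o$df$outc_cod))
  bad_outc <- !(o$df$outc_cod %in% OUTCOME_CODES)
  o$df <- o$df[!bad_outc, , drop = FALSE]

  d$df$role_cod <- toupper(trimws(d$df$role_cod))

  demo_parsed <- data.frame(
    primaryid = demo$primaryid,
    caseid = demo$caseid,
    fda_dt = demo$fda_dt %||% "",
    event_dt = demo$event_dt %||% "",
    sex = toupper(trimws(demo$sex %||% "")),
    age_years = parse_age_years(demo$age %||% "", demo$age_cod %||% ""),
    weight_kg = parse_weight_kg(demo$wt %||% ""),
    country = toupper(trimws(demo$reporter_country %||% "")),
    occp_cod = toupper(trimws(demo$occp_cod %||% "")),
    stringsAsFactors = FALSE)
  rownames(demo_parsed) <- NULL

  structure(list(
    demo = demo_parsed,
    drugs = d$df,
    reactions = r$df,
    outcomes = o$df,
    therapies = t$df,
    anomalies = list(orphan_drug = d$orphans, orphan_reac = r$orphans,
                     orphan_outc = o$orphans, orphan_ther = t$orphans,
                     empty_pt = sum(bad_pt), bad_outcome_code = sum(bad_outc))),
    class = "faers_cases")
}

#' @export
print.faers_cases <- function(x, ...) {
  cat(sprintf("faers_cases: %d cases, %d drug rows, %d reactions, %d outcome entries, %d therapy rows\n",
              nrow(x$demo), nrow(x$drugs), nrow(x$reactions),
              nrow(x$outcomes), nrow(x$therapies)))
  an <- unlist(x$anomalies)
  if (any(an > 0))
    cat("anomalies:", paste(names(an)[an > 0], an[an > 0], sep = "=",
                            collapse = ", "), "\n")
  invisible(x)
}

#' Read, dedupe and link a FAERS-format directory in one call
#'
#' Convenience wrapper: reads the six tables written by
#' [generate_faers_dataset()] (or any directory in the same layout),
#' applies the deleted-case list if present, deduplicates and links.
#'
#' @param dir directory containing `DEMO.txt`, `DRUG.txt`, `REAC.txt`,
#'   `OUTC.txt`, `THER.txt` (and optionally `deleted_cases.txt`).
#' @return a `faers_cases` object (see [link_cases()]).
#' @export
read_faers_dir <- function(dir) {
  p <- function(nm) {
    f <- file.path(dir, paste0(nm, ".txt"))
    if (!file.exists(f) && file.exists(paste0(f, ".gz"))) f <- paste0(f, ".gz")
    f
  }
  demo <- read_faers_table(p("DEMO"), "DEMO")
  deleted <- character()
  del_path <- file.path(dir, "deleted_cases.txt")
  if (file.exists(del_path)) deleted <- read_deleted_cases(del_path)
  demo <- dedupe_demo(demo, deleted)
  link_cases(demo,
             read_faers_table(p("DRUG"), "DRUG"),
             read_faers_table(p("REAC"), "REAC"),
             read_faers_table(p("OUTC"), "OUTC"),
             read_faers_table(p("THER"), "THER"))
}
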