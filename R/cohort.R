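#' Cohort configuration: target-drug keywords and roles
#'
#' A report enters the cohort when at least one of its drug mentions has a
#' name (trade or active-ingredient field) containing a keyword — matching
#' is case-insensitive after collapsing internal whitespace and hyphens,
#' so "DCC 2618" matches "DCC-2618" — and that same drug's role code is in
#' `roles`. The default restricts to primary suspect (PS) drugs, the
#' single-factor attribution used in most FAERS disproportionality work.
#'
#' @param keywords non-empty character vector of drug-name keywords.
#' @param roles non-empty subset of `c("PS", "SS", "C", "I")`.
#' @return an object of class `cohort_config`.
#' @export
cohort_config <- function(keywords, roles = "PS") {
  if (length(keywords) == 0 || !is.character(keywords) ||
      any(!nzchar(trimws(keywords))))
    stop_field("keywords", "must be a non-empty character vector")
  roles <- toupper(roles)
  if (length(roles) == 0 || !all(roles %in% c("PS", "SS", "C", "I")))
    stop_field("roles", "must be a non-empty subset of PS, SS, C, I")
  structure(list(keywords = keywords, roles = roles),
            class = "cohort_config")
}

#' Identify target-drug reports
#'
#' @param cases a `faers_cases` object ([link_cases()]).
#' @param config a [cohort_config()].
#' @return character vector of PRIMARYIDs of matched reports (possibly
#'   empty), sorted.
#' @export
match_target_reports <- function(cases, config) {
  stopifnot(inherits(cases, "faers_cases"), inherits(config, "cohort_config"))
  dr <- cases$drugs
  if (nrow(dr) == 0) return(character())
  kw <- normalize_drugname(config$keywords)
  nm1 <- normalize_drugname(dr$drugname)
  nm2 <- normalize_drugname(dr$prod_ai)
  hit <- rep(FALSE, nrow(dr))
  for (k in kw)
    hit <- hit | grepl(k, nm1, fixed = TRUE) | grepl(k, nm2, fixed = TRUE)
  hit <- hit & dr$role_cod %in% config$roles
  sort(unique(dr$primaryid[hit]))
}

#' Load a PT-to-SOC mapping file
#'
#' Two-column tab-separated file (`pt<TAB>soc`); a header line is detected
#' and skipped if its first field is "pt" (case-insensitive). Lookup keys
#' are whitespace-normalized and case-folded; the original casing is kept
#' for output. A PT mapped to two different SOCs is a hard error.
#'
#' @param path path to the mapping file.
#' @return an object of class `meddra_map`.
#' @export
load_meddra_map <- function(path) {
  raw <- utils::read.delim(path, header = FALSE, sep = "\t",
                           quote = "", colClasses = "character")
  if (ncol(raw) < 2) stop("mapping file must have two tab-separated columns",
                          call. = FALSE)
  if (nrow(raw) > 0 && tolower(trimws(raw[1, 1])) == "pt")
    raw <- raw[-1, , drop = FALSE]
  map <- data.frame(pt = normalize_term(raw[[1]]),
                    soc = normalize_term(raw[[2]]), stringsAsFactors = FALSE)
  map$key <- tolower(map$pt)
  map <- unique(map)
  if (anyDuplicated(map$key))
    stop("conflicting SOC assignments for PT(s): ",
         paste(unique(map$pt[duplicated(map$key)]), collapse = ", "),
         call. = FALSE)
  structure(map, class = c("meddra_map", "data.frame"))
}

#' Map PTs to SOCs
#'
#' Unmapped PTs are assigned the sentinel SOC `"UNMAPPED"` and counted in
#' the `n_unmapped` attribute.
#'
#' @param map a `meddra_map` from [load_meddra_map()].
#' @param pts character vector of PT strings.
#' @return character vector of SOC names with attribute `n_unmapped`.
#' @export
map_pt_to_soc <- function(map, pts) {
  idx <- match(tolower(normalize_term(pts)), map$key)
  soc <- map$soc[idx]
  soc[is.na(idx)] <- "UNMAPPED"
  structure(soc, n_unmapped = sum(is.na(idx)))
}

#' Count distinct-report events at PT and SOC level
#'
#' Produces the margins of every downstream 2x2 table. All counts are over
#' DISTINCT deduplicated reports: a report mentioning a PT twice counts
#' once, and a report with two PTs in the same SOC counts once at SOC
#' level. `n_target` is the count among target-drug reports, `n_total`
#' across the whole database.
#'
#' @param cases a `faers_cases` object.
#' @param target_ids PRIMARYIDs from [match_target_reports()].
#' @param meddra_map a `meddra_map`; used for SOC aggregation.
#' @return an `event_counts` object: list with data.frames `pt` and `soc`
#'   (columns `term`, `n_target`, `n_total`), scalars `n_target_total` and
#'   `n_all`, and the unmapped-PT tally.
#' @export
count_events <- function(cases, target_ids, meddra_map) {
  stopifnot(inherits(cases, "faers_cases"))
  rx <- cases$reactions
  is_target <- rx$primaryid %in% target_ids

  count_level <- function(term) {
    keep <- !duplicated(paste(rx$primaryid, term, sep = "\r"))
    tt <- term[keep]
    tg <- is_target[keep]
    tot <- table(tt)
    tar <- table(tt[tg])
    out <- data.frame(term = names(tot),
                      n_target = as.integer(tar[names(tot)]),
                      n_total = as.integer(tot), stringsAsFactors = FALSE)
    out$n_target[is.na(out$n_target)] <- 0L
    out[order(out$term, method = "radix"), , drop = FALSE]
  }

  soc <- map_pt_to_soc(meddra_map, rx$pt)
  structure(list(
    pt = count_level(rx$pt),
    soc = count_level(as.character(soc)),
    n_target_total = length(intersect(target_ids, cases$demo$primaryid)),
    n_all = nrow(cases$demo),
    n_unmapped = attr(soc, "n_unmapped")), class = "event_counts")
}

#' @export
print.event_counts <- function(x, ...) {
  cat(sprintf("event_counts: %d PTs, %d SOCs; %d target reports of %d total\n",
              nrow(x$pt), nrow(x$soc), x$n_target_total, x$n_all))
  invisible(x)
}
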