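#' Demographic and outcome summary of a cohort
#'
#' Tabulates the cohort by sex, weight band (<50 / 50-100 / >100 kg), age
#' band (<18 / 18-64.9 / 65-85 / >85 years), reporter occupation (consumer
#' vs health professional), reporting country and outcome code, each with
#' counts and percentages plus a missing row. Percentages for sex, weight,
#' age, occupation and country use the number of cohort reports as
#' denominator; outcome percentages use the total number of outcome
#' ENTRIES — a report may carry several outcome codes, and a report with
#' none contributes one "Missing" entry — which is the only denominator
#' under which published FAERS outcome tables are internally consistent.
#'
#' @param cases a `faers_cases` object.
#' @param cohort_ids PRIMARYIDs of the cohort ([match_target_reports()]).
#' @return a `demographics_summary`: named list of data.frames
#'   (`sex`, `weight`, `age`, `occupation`, `country`, `outcome`), each
#'   with columns `label`, `count`, `percent`, plus `n_reports` and
#'   `n_outcome_entries`.
#' @export
summarize_demographics <- function(cases, cohort_ids) {
  stopifnot(inherits(cases, "faers_cases"))
  demo <- cases$demo[cases$demo$primaryid %in% cohort_ids, , drop = FALSE]
  n <- nrow(demo)
  pct <- function(count, den) if (den > 0) round(100 * count / den, 1) else 0

  tab_of <- function(labels, order_labels) {
    cnt <- table(factor(labels, levels = order_labels))
    data.frame(label = order_labels, count = as.integer(cnt),
               percent = vapply(as.integer(cnt), pct, numeric(1), den = n),
               stringsAsFactors = FALSE)
  }

  sex_lab <- ifelse(demo$sex %in% c("M", "F"),
                    ifelse(demo$sex == "M", "Male", "Female"), "Missing")
  sex_df <- tab_of(sex_lab, c("Male", "Female", "Missing"))

  w <- demo$weight_kg
  wt_lab <- ifelse(is.na(w), "Missing",
            ifelse(w < 50, "<50", ifelse(w <= 100, "50-100", ">100")))
  wt_df <- tab_of(wt_lab, c("<50", "50-100", ">100", "Missing"))

  ag <- demo$age_years
  age_lab <- ifelse(is.na(ag), "Missing",
             ifelse(ag < 18, "<18",
             ifelse(ag < 65, "18-64.9",
             ifelse(ag <= 85, "65-85", ">85"))))
  age_df <- tab_of(age_lab, c("<18", "18-64.9", "65-85", ">85", "Missing"))

  occ <- demo$occp_cod
  occ_lab <- ifelse(!nzchar(occ), "Missing",
             ifelse(occ %in% c("CN", "LW"), "Consumer", "Health professional"))
  occ_df <- tab_of(occ_lab, c("Consumer", "Health professional", "Missing"))

  ctry <- ifelse(nzchar(demo$country), demo$country, "Missing")
  ctab <- sort(table(ctry), decreasing = TRUE)
  ctry_df <- data.frame(label = names(ctab), count = as.integer(ctab),
                        percent = vapply(as.integer(ctab), pct, numeric(1),
                                         den = n), stringsAsFactors = FALSE)

  oc <- cases$outcomes[cases$outcomes$primaryid %in% cohort_ids, , drop = FALSE]
  n_missing_outcome <- n - length(unique(oc$primaryid))
  n_entries <- nrow(oc) + n_missing_outcome
  outcome_names <- c(DE = "Death", LT = "Life-threatening",
                     HO = "Hospitalization", DS = "Disability",
                     CA = "Congenital anomaly", RI = "Required intervention",
                     OT = "Other")
  ocnt <- table(factor(oc$outc_cod, levels = names(outcome_names)))
  out_df <- data.frame(label = c(unname(outcome_names), "Missing"),
                       count = c(as.integer(ocnt), n_missing_outcome),
                       stringsAsFactors = FALSE)
  out_df$percent <- vapply(out_df$count, pct, numeric(1), den = n_entries)
  out_df <- out_df[out_df$count > 0 | out_df$label == "Missing", , drop = FALSE]
  rownames(out_df) <- NULL

  structure(list(sex = sex_df, weight = wt_df, age = age_df,
                 occupation = occ_df, country = ctry_df, outcome = out_df,
                 n_reports = n, n_outcome_entries = n_entries),
            class = "demographics_summary")
}

#' @export
print.demographics_summary <- function(x, ...) {
  cat(sprintf("Cohort of %d reports (%d outcome entries)\n",
              x$n_reports, x$n_outcome_entries))
  for (nm in c("sex", "weight", "age", "occupation", "country", "outcome")) {
    cat("--", nm, "--\n")
    print(x[[nm]], row.names = FALSE)
  }
  invisible(x)
}

#' Days from therapy start to adverse event, per cohort report
#'
#' For each cohort report, onset is the difference between the event date
#' (DEMO) and the EARLIEST full-precision therapy start date among the
#' therapy rows linked to a target drug (the drug rows whose name matches
#' the cohort keywords and roles). Reports with a missing event date,
#' missing start date, a partial (month- or year-precision) date on either
#' side, or a negative interval are excluded with a tagged reason; the
#' exclusion accounting mirrors the "inaccurate, missing, or unknown"
#' filter applied in onset analyses of spontaneous reports.
#'
#' @param cases a `faers_cases` object.
#' @param cohort_ids PRIMARYIDs of the cohort.
#' @param config the [cohort_config()] identifying target drugs.
#' @return data.frame with one row per cohort report: `primaryid`, `days`
#'   (NA when excluded) and `reason` (one of `missing_event_date`,
#'   `missing_start_date`, `partial_date`, `negative_interval`, or NA when
#'   included). Exclusion tallies are in the `exclusions` attribute.
#' @export
onset_days <- function(cases, cohort_ids, config) {
  stopifnot(inherits(cases, "faers_cases"), inherits(config, "cohort_config"))
  demo <- cases$demo[cases$demo$primaryid %in% cohort_ids, , drop = FALSE]
  dr <- cases$drugs
  kw <- normalize_drugname(config$keywords)
  nm1 <- normalize_drugname(dr$drugname)
  nm2 <- normalize_drugname(dr$prod_ai)
  hit <- rep(FALSE, nrow(dr))
  for (k in kw)
    hit <- hit | grepl(k, nm1, fixed = TRUE) | grepl(k, nm2, fixed = TRUE)
  hit <- hit & dr$role_cod %in% config$roles
  target_drug <- dr[hit, c("primaryid", "drug_seq"), drop = FALSE]
  ther <- cases$therapies
  ther_key <- paste(ther$primaryid, ther$dsg_drug_seq, sep = "\r")
  target_key <- paste(target_drug$primaryid, target_drug$drug_seq, sep = "\r")
  ther <- ther[ther_key %in% target_key, , drop = FALSE]

  one <- function(pid, event_dt) {
    st <- ther$start_dt[ther$primaryid == pid]
    ev_prec <- date_precision(event_dt)
    if (!length(st) || all(!nzchar(st)))
      return(list(days = NA_integer_, reason = "missing_start_date"))
    st <- st[nzchar(st)]
    prec <- date_precision(st)
    if (!any(prec == 8L)) {
      # only partial-precision starts available
      return(list(days = NA_integer_, reason = "partial_date"))
    }
    if (ev_prec == 0L) {
      if (nzchar(event_dt))
        return(list(days = NA_integer_, reason = "missing_event_date"))
      return(list(days = NA_integer_, reason = "missing_event_date"))
    }
    if (ev_prec != 8L)
      return(list(days = NA_integer_, reason = "partial_date"))
    st8 <- min(st[prec == 8L])
    d <- days_between(st8, event_dt)
    if (is.na(d)) return(list(days = NA_integer_, reason = "partial_date"))
    if (d < 0) return(list(days = NA_integer_, reason = "negative_interval"))
    list(days = d, reason = NA_character_)
  }
  res <- Map(one, demo$primaryid, demo$event_dt)
  out <- data.frame(primaryid = demo$primaryid,
                    days = vapply(res, function(x) x$days, integer(1)),
                    reason = vapply(res, function(x) x$reason, character(1)),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  excl <- table(out$reason[!is.na(out$reason)])
  attr(out, "exclusions") <- as.list(excl)
  out
}

#' Attach PT/SOC labels and bins to onset intervals
#'
#' Expands per-report onset days into one record per (report, PT) pair so
#' onset can be summarized per SOC; excluded reports are dropped.
#'
#' @param cases a `faers_cases` object.
#' @param onset result of [onset_days()].
#' @param meddra_map a `meddra_map`.
#' @param bin_edges passed to [onset_bins()].
#' @return data.frame: `primaryid`, `days`, `pt`, `soc`, `bin`.
#' @export
onset_records <- function(cases, onset, meddra_map,
                          bin_edges = default_onset_bins()) {
  keep <- onset[!is.na(onset$days), , drop = FALSE]
  rx <- cases$reactions
  rx <- rx[rx$primaryid %in% keep$primaryid, , drop = FALSE]
  rx <- rx[!duplicated(paste(rx$primaryid, rx$pt, sep = "\r")), , drop = FALSE]
  days <- keep$days[match(rx$primaryid, keep$primaryid)]
  soc <- as.character(map_pt_to_soc(meddra_map, rx$pt))
  out <- data.frame(primaryid = rx$primaryid, days = days, pt = rx$pt,
                    soc = soc, bin = onset_bins(days, bin_edges),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' @rdname onset_summary
#' @export
default_onset_bins <- function() c(0, 30, 60, 90, 120, 150, 180, 360)

#' Label onset days by monthly bin
#'
#' A month is 30 days; the default bins are 0-1, 1-2, ..., 5-6 months,
#' one coarse 6-12-month bin, and an overflow bin beyond the last edge.
#'
#' @param days non-negative integer vector.
#' @param edges increasing bin lower edges starting at 0.
#' @return character vector of bin labels (e.g. `"0-1 m"`, `">12 m"`).
#' @export
onset_bins <- function(days, edges = default_onset_bins()) {
  labels <- c(paste0(edges[-length(edges)] / 30, "-", edges[-1] / 30, " m"),
              paste0(">", edges[length(edges)] / 30, " m"))
  idx <- findInterval(days, c(edges, Inf))
  labels[idx]
}

#' Summarize time to onset
#'
#' Median and quartiles use the (n+1)p linear-interpolation convention
#' (R `quantile` type 6); bins report counts and percentages over records
#' with known onset.
#'
#' @param days integer vector of onset days (NAs dropped).
#' @param bin_edges increasing lower bin edges starting at 0.
#' @return an `onset_summary`: list with `n`, `median`, `q1`, `q3` and a
#'   `bins` data.frame (`bin`, `count`, `percent`); all-NA or empty input
#'   yields the explicit empty summary (`n = 0`, NA quantiles, empty bins).
#' @export
onset_summary <- function(days, bin_edges = default_onset_bins()) {
  days <- days[!is.na(days)]
  labels <- c(paste0(bin_edges[-length(bin_edges)] / 30, "-",
                     bin_edges[-1] / 30, " m"),
              paste0(">", bin_edges[length(bin_edges)] / 30, " m"))
  if (length(days) == 0) {
    return(structure(list(n = 0L, median = NA_real_, q1 = NA_real_,
                          q3 = NA_real_,
                          bins = data.frame(bin = labels, count = 0L,
                                            percent = 0,
                                            stringsAsFactors = FALSE)),
                     class = "onset_summary"))
  }
  q <- stats::quantile(days, c(0.25, 0.5, 0.75), type = 6, names = FALSE)
  cnt <- table(factor(onset_bins(days, bin_edges), levels = labels))
  structure(list(
    n = length(days), median = q[2], q1 = q[1], q3 = q[3],
    bins = data.frame(bin = labels, count = as.integer(cnt),
                      percent = round(100 * as.integer(cnt) / length(days), 2),
                      stringsAsFactors = FALSE)),
    class = "onset_summary")
}

#' @export
print.onset_summary <- function(x, ...) {
  cat(sprintf("n=%d, median %s days (IQR %s-%s)\n", x$n,
              format(x$median), format(x$q1), format(x$q3)))
  print(x$bins, row.names = FALSE)
  invisible(x)
}

#' Per-SOC onset distributions
#'
#' @param records onset records from [onset_records()].
#' @return data.frame, one row per SOC ordered by `n` descending (ties by
#'   SOC name): `soc`, `n`, `median`, `q1`, `q3`.
#' @export
onset_by_soc <- function(records) {
  if (nrow(records) == 0)
    return(data.frame(soc = character(), n = integer(), median = numeric(),
                      q1 = numeric(), q3 = numeric(), stringsAsFactors = FALSE))
  socs <- split(records$days, records$soc)
  out <- do.call(rbind, lapply(names(socs), function(s) {
    q <- stats::quantile(socs[[s]], c(0.25, 0.5, 0.75), type = 6,
                         names = FALSE)
    data.frame(soc = s, n = length(socs[[s]]), median = q[2], q1 = q[1],
               q3 = q[3], stringsAsFactors = FALSE)
  }))
  out <- out[order(-out$n, out$soc, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}
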