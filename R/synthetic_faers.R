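#' Simulation configuration for the synthetic FAERS generator
#'
#' Builds and validates the configuration driving [generate_faers_dataset()].
#' The generator emulates the multi-table structure of FAERS quarterly data:
#' cases keyed by CASEID with one or more PRIMARYID versions, suspect and
#' concomitant drug roles, MedDRA-coded reactions with configurable
#' background reporting frequencies, planted drug-event reporting-rate
#' multipliers, categorical demographics, outcome codes, and therapy-start /
#' event dates with a two-component (early/late) Weibull onset mixture.
#'
#' Reports are generated case-first: demographics are sampled, then drug
#' exposures, then reactions per report with the planted multipliers applied,
#' so the expected 2x2 cell counts downstream are analytic. A report that
#' draws no catalog drug receives the filler drug `"UNSPECIFIED MEDICATION"`
#' and a report that draws no catalog reaction receives the filler PT
#' `"Unspecified adverse event"`; fillers sit outside the catalog so planted
#' conditional probabilities stay exact (for a planted (drug, PT, lambda)
#' pair, P(PT | exposed to drug) = min(1, lambda * background)).
#'
#' @param n_reports number of distinct cases to generate (>= 1).
#' @param drugs data.frame with columns `name` and `p` (marginal exposure
#'   probability per report).
#' @param events data.frame with columns `pt`, `soc`, `p` (background
#'   per-report reporting probability of the PT).
#' @param signals data.frame with columns `drug`, `pt`, `lambda`; lambda is
#'   the reporting-rate multiplier (lambda = 1 means no association,
#'   lambda >= 0). Probabilities are capped at 1; capping is reported in the
#'   returned ground truth.
#' @param demographics list of categorical distributions: `sex` (M/F/UNK),
#'   `age_band`, `weight_band`, `country`, `occupation` (FAERS occp_cod),
#'   `outcomes` (outcome codes plus `"none"`). Each must sum to 1.
#' @param onset onset-day model: `mix` (probability of the early component),
#'   `shape_early`/`scale_early` and `shape_late`/`scale_late` Weibull
#'   parameters in days, and optionally `by_soc`, a named list of per-SOC
#'   overrides with the same five fields. The onset day of a case is drawn
#'   from the model of the SOC of its first catalog reaction.
#' @param duplicate_fraction proportion of cases emitted as two versions
#'   (an extra earlier-dated PRIMARYID; clinical content identical).
#' @param deleted_fraction proportion (of `n_reports`) of EXTRA cases
#'   generated and listed in the deleted-case file, so removal recovers
#'   exactly `n_reports` cases.
#' @param missing_rates per-field missingness probabilities: `event_dt`,
#'   `start_dt`, `age`, `wt`, `country`, `occp`.
#' @param partial_date_fraction among non-missing event/start dates, the
#'   fraction emitted at month (6-digit) or year (4-digit) precision.
#' @param seed integer RNG seed; identical config + seed yields
#'   byte-identical output files.
#' @return a validated object of class `sim_config`.
#' @export
sim_config <- function(n_reports = 2000,
                       drugs = default_drug_catalog(),
                       events = default_event_catalog(),
                       signals = default_planted_signals(),
                       demographics = default_demographics(),
                       onset = default_onset_model(),
                       duplicate_fraction = 0.1,
                       deleted_fraction = 0.02,
                       missing_rates = default_missing_rates(),
                       partial_date_fraction = 0.05,
                       seed = 1L) {
  cfg <- structure(list(
    n_reports = n_reports, drugs = drugs, events = events, signals = signals,
    demographics = demographics, onset = onset,
    duplicate_fraction = duplicate_fraction,
    deleted_fraction = deleted_fraction,
    missing_rates = missing_rates,
    partial_date_fraction = partial_date_fraction,
    seed = as.integer(seed)), class = "sim_config")
  validate_sim_config(cfg)
  cfg
}

#' @rdname sim_config
#' @export
default_drug_catalog <- function() {
  data.frame(
    name = c("RIPRETINIB", "IMATINIB", "SUNITINIB", "REGORAFENIB",
             "OMEPRAZOLE", "METFORMIN"),
    p = c(0.12, 0.10, 0.08, 0.06, 0.15, 0.18),
    stringsAsFactors = FALSE)
}

#' @rdname sim_config
#' @export
default_event_catalog <- function() {
  pts <- c("Fatigue", "Nausea", "Diarrhoea", "Alopecia", "Constipation",
           "Vomiting", "Decreased appetite", "Muscle spasms", "Myalgia",
           "Pain in extremity", "Dry skin",
           "Palmar-plantar erythrodysaesthesia syndrome", "Pruritus",
           "Rash", "Hypertension", "Weight decreased", "Headache",
           "Dizziness", "Anaemia", "Hepatic neoplasm")
  socs <- c("General disorders and administration site conditions",
            "Gastrointestinal disorders", "Gastrointestinal disorders",
            "Skin and subcutaneous tissue disorders",
            "Gastrointestinal disorders", "Gastrointestinal disorders",
            "Metabolism and nutrition disorders",
            "Musculoskeletal and connective tissue disorders",
            "Musculoskeletal and connective tissue disorders",
            "Musculoskeletal and connective tissue disorders",
            "Skin and subcutaneous tissue disorders",
            "Skin and subcutaneous tissue disorders",
            "Skin and subcutaneous tissue disorders",
            "Skin and subcutaneous tissue disorders",
            "Vascular disorders", "Investigations",
            "Nervous system disorders", "Nervous system disorders",
            "Blood and lymphatic system disorders",
            "Neoplasms benign, malignant and unspecified")
  # Zipf-like background frequencies: common PTs dominate, a long tail.
  p <- 0.06 / seq_along(pts)^0.8
  data.frame(pt = pts, soc = socs, p = p, stringsAsFactors = FALSE)
}

#' @rdname sim_config
#' @export
default_planted_signals <- function() {
  data.frame(
    drug = "RIPRETINIB",
    pt = c("Alopecia", "Palmar-plantar erythrodysaesthesia syndrome",
           "Muscle spasms", "Dry skin", "Fatigue", "Constipation"),
    lambda = c(10, 25, 6, 5, 3, 4.5),
    stringsAsFactors = FALSE)
}

#' @rdname sim_config
#' @export
default_demographics <- function() {
  list(
    sex = c(M = 0.539, F = 0.44, UNK = 0.021),
    age_band = c("<18" = 0.01, "18-64.9" = 0.39, "65-85" = 0.565,
                 ">85" = 0.035),
    weight_band = c("<50" = 0.115, "50-100" = 0.821, ">100" = 0.064),
    country = c(US = 0.929, FR = 0.017, CA = 0.015, DE = 0.005, GB = 0.005,
                JP = 0.029),
    occupation = c(CN = 0.597, MD = 0.25, PH = 0.101, OT = 0.052),
    outcomes = c(none = 0.575, HO = 0.176, OT = 0.147, DE = 0.096,
                 LT = 0.005, DS = 0.001))
}

#' @rdname sim_config
#' @export
default_onset_model <- function() {
  list(mix = 0.45, shape_early = 0.9, scale_early = 35,
       shape_late = 1.6, scale_late = 320, by_soc = list())
}

#' @rdname sim_config
#' @export
default_missing_rates <- function() {
  list(event_dt = 0.30, start_dt = 0.15, age = 0.62, wt = 0.90,
       country = 0.01, occp = 0.002)
}

check_dist <- function(x, field) {
  if (is.null(names(x)) || any(!nzchar(names(x))))
    stop_field(field, "must be a named probability vector")
  if (any(x < 0 | x > 1))
    stop_field(field, "probabilities must lie in [0, 1]")
  if (abs(sum(x) - 1) > 1e-9)
    stop_field(field, sprintf("probabilities must sum to 1 (got %.12f)", sum(x)))
  invisible(TRUE)
}

#' Validate a simulation configuration
#'
#' @param cfg a `sim_config` (or bare list with the same fields).
#' @return the config, invisibly, if valid; otherwise an error naming the
#'   offending field.
#' @export
validate_sim_config <- function(cfg) {
  if (!is.numeric(cfg$n_reports) || length(cfg$n_reports) != 1 ||
      is.na(cfg$n_reports) || cfg$n_reports < 1)
    stop_field("n_reports", "must be a single integer >= 1")
  d <- cfg$drugs
  if (!is.data.frame(d) || !all(c("name", "p") %in% names(d)) || nrow(d) < 1)
    stop_field("drugs", "must be a data.frame with columns name, p")
  if (anyDuplicated(d$name)) stop_field("drugs", "drug names must be unique")
  if (any(d$p < 0 | d$p > 1)) stop_field("drugs", "probabilities must lie in [0, 1]")
  e <- cfg$events
  if (!is.data.frame(e) || !all(c("pt", "soc", "p") %in% names(e)) || nrow(e) < 1)
    stop_field("events", "must be a data.frame with columns pt, soc, p")
  if (anyDuplicated(e$pt)) stop_field("events", "PT names must be unique")
  if (any(e$p < 0 | e$p > 1)) stop_field("events", "probabilities must lie in [0, 1]")
  s <- cfg$signals
  if (!is.null(s) && nrow(s) > 0) {
    if (!all(c("drug", "pt", "lambda") %in% names(s)))
      stop_field("signals", "must have columns drug, pt, lambda")
    if (any(s$lambda < 0)) stop_field("signals", "lambda must be >= 0")
    bad <- setdiff(s$drug, d$name)
    if (length(bad))
      stop_field("signals", paste("unknown drug in planted signals:",
                                  paste(bad, collapse = ", ")))
    bad <- setdiff(s$pt, e$pt)
    if (length(bad))
      stop_field("signals", paste("unknown PT in planted signals:",
                                  paste(bad, collapse = ", ")))
    if (anyDuplicated(s[c("drug", "pt")]))
      stop_field("signals", "duplicate (drug, pt) pair")
  }
  dm <- cfg$demographics
  for (f in c("sex", "age_band", "weight_band", "country", "occupation",
              "outcomes"))
    check_dist(dm[[f]], paste0("demographics$", f))
  if (!all(names(dm$age_band) %in% c("<18", "18-64.9", "65-85", ">85")))
    stop_field("demographics$age_band",
               "bands must be among <18, 18-64.9, 65-85, >85")
  if (!all(names(dm$weight_band) %in% c("<50", "50-100", ">100")))
    stop_field("demographics$weight_band",
               "bands must be among <50, 50-100, >100")
  on <- cfg$onset
  for (f in c("mix", "shape_early", "scale_early", "shape_late", "scale_late"))
    if (!is.numeric(on[[f]]) || length(on[[f]]) != 1 || is.na(on[[f]]))
      stop_field(paste0("onset$", f), "must be a single number")
  if (on$mix < 0 || on$mix > 1) stop_field("onset$mix", "must lie in [0, 1]")
  for (f in c("duplicate_fraction", "deleted_fraction",
              "partial_date_fraction")) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0 || v > 1)
      stop_field(f, "must lie in [0, 1]")
  }
  for (f in names(cfg$missing_rates)) {
    v <- cfg$missing_rates[[f]]
    if (!is.numeric(v) || v < 0 || v > 1)
      stop_field(paste0("missing_rates$", f), "must lie in [0, 1]")
  }
  invisible(cfg)
}

FILLER_DRUG <- "UNSPECIFIED MEDICATION"
FILLER_PT <- "Unspecified adverse event"
FILLER_SOC <- "General disorders and administration site conditions"
SIM_EPOCH <- as.Date("2020-05-01")

sample_cat <- function(n, dist) {
  names(dist)[sample.int(length(dist), n, replace = TRUE, prob = dist)]
}

onset_params_for <- function(onset, soc) {
  ov <- onset$by_soc[[soc]]
  if (is.null(ov)) onset else utils::modifyList(onset, ov)
}

# Draw one onset day per case from the mixture of the SOC-specific model.
draw_onset_days <- function(socs, onset) {
  n <- length(socs)
  days <- integer(n)
  for (soc in unique(socs)) {
    idx <- which(socs == soc)
    p <- onset_params_for(onset, soc)
    early <- stats::runif(length(idx)) < p$mix
    d <- numeric(length(idx))
    d[early] <- stats::rweibull(sum(early), p$shape_early, p$scale_early)
    d[!early] <- stats::rweibull(sum(!early), p$shape_late, p$scale_late)
    days[idx] <- as.integer(round(d))
  }
  days
}

#' Simulate FAERS-format tables in memory
#'
#' The workhorse behind [generate_faers_dataset()]: returns the seven-table
#' case structure as character data.frames plus the ground truth, without
#' touching the file system. Useful for replicate studies (calibration,
#' signal recovery) where file I/O would dominate.
#'
#' @param config a [sim_config()].
#' @return list with `tables` (named list: demo, drug, reac, outc, ther,
#'   indi — character data.frames in the FAERS column dialect),
#'   `deleted_caseids` (character), and `ground_truth` (see
#'   [generate_faers_dataset()]).
#' @export
simulate_faers_tables <- function(config) {
  validate_sim_config(config)
  with_seed(config$seed, simulate_faers_tables_impl(config))
}

simulate_faers_tables_impl <- function(config) {
  n <- as.integer(config$n_reports)
  n_del <- as.integer(round(config$deleted_fraction * n))
  ncase <- n + n_del
  drugs <- config$drugs
  events <- config$events
  dm <- config$demographics
  mr <- config$missing_rates
  K <- nrow(drugs)
  J <- nrow(events)

  caseid <- 20000000L + seq_len(ncase)
  deleted <- c(rep(FALSE, n), rep(TRUE, n_del))

  ## demographics -----------------------------------------------------------
  sex <- sample_cat(ncase, dm$sex)
  sex_out <- ifelse(sex == "UNK", "", sex)
  age_band <- sample_cat(ncase, dm$age_band)
  age_lo <- c("<18" = 2, "18-64.9" = 18, "65-85" = 65, ">85" = 85.1)[age_band]
  age_hi <- c("<18" = 17.9, "18-64.9" = 64.9, "65-85" = 85, ">85" = 99)[age_band]
  age <- round(age_lo + stats::runif(ncase) * (age_hi - age_lo), 1)
  wt_band <- sample_cat(ncase, dm$weight_band)
  wt_lo <- c("<50" = 35, "50-100" = 50, ">100" = 100.1)[wt_band]
  wt_hi <- c("<50" = 49.9, "50-100" = 100, ">100" = 140)[wt_band]
  wt <- round(wt_lo + stats::runif(ncase) * (wt_hi - wt_lo), 1)
  country <- sample_cat(ncase, dm$country)
  occp <- sample_cat(ncase, dm$occupation)
  outc1 <- sample_cat(ncase, dm$outcomes)

  ## drug exposure ----------------------------------------------------------
  expo <- matrix(stats::runif(ncase * K), ncase, K) <
    matrix(drugs$p, ncase, K, byrow = TRUE)
  no_drug <- rowSums(expo) == 0L

  ## reactions with planted multipliers -------------------------------------
  eff <- matrix(events$p, ncase, J, byrow = TRUE)
  n_capped <- 0L
  sig <- config$signals
  if (!is.null(sig) && nrow(sig) > 0) {
    for (j in unique(match(sig$pt, events$pt))) {
      rows_sig <- sig[match(sig$pt, events$pt) == j, , drop = FALSE]
      lam_rep <- rep(1, ncase)
      for (r in seq_len(nrow(rows_sig))) {
        k <- match(rows_sig$drug[r], drugs$name)
        lam_rep[expo[, k]] <- pmax(lam_rep[expo[, k]], rows_sig$lambda[r])
      }
      p_eff <- events$p[j] * lam_rep
      n_capped <- n_capped + sum(p_eff > 1)
      eff[, j] <- pmin(1, p_eff)
    }
  }
  reac <- matrix(stats::runif(ncase * J), ncase, J) < eff
  no_reac <- rowSums(reac) == 0L

  ## onset + dates ----------------------------------------------------------
  first_pt <- max.col(reac, ties.method = "first")  # arbitrary when row empty
  onset_soc <- ifelse(no_reac, FILLER_SOC, events$soc[first_pt])
  onset_day <- draw_onset_days(onset_soc, config$onset)
  start_date <- SIM_EPOCH + (sample.int(1400L, ncase, replace = TRUE) - 1L)
  event_date <- start_date + onset_day
  fda_date <- event_date + (sample.int(91L, ncase, replace = TRUE) - 1L)
  start_dt <- format(start_date, "%Y%m%d")
  event_dt <- format(event_date, "%Y%m%d")
  fda_dt <- format(fda_date, "%Y%m%d")

  degrade_date <- function(x) {
    keep <- nzchar(x)
    part <- keep & stats::runif(ncase) < config$partial_date_fraction
    to_year <- part & stats::runif(ncase) < 0.3
    x[part] <- substr(x[part], 1L, 6L)
    x[to_year] <- substr(x[to_year], 1L, 4L)
    x
  }
  event_dt[stats::runif(ncase) < mr$event_dt] <- ""
  event_dt <- degrade_date(event_dt)
  start_dt_case <- start_dt
  start_dt_case[stats::runif(ncase) < mr$start_dt] <- ""
  start_dt_case <- degrade_date(start_dt_case)
  age_out <- ifelse(stats::runif(ncase) < mr$age, "", format(age))
  wt_out <- ifelse(stats::runif(ncase) < mr$wt, "", format(wt))
  country_out <- ifelse(stats::runif(ncase) < mr$country, "", country)
  occp_out <- ifelse(stats::runif(ncase) < mr$occp, "", occp)

  ## versions / duplicates --------------------------------------------------
  is_dup <- stats::runif(ncase) < config$duplicate_fraction
  n_versions <- ifelse(is_dup, 2L, 1L)
  canonical_pid <- caseid * 100L + n_versions

  ## per-case drug rows (roles assigned among exposed + filler) -------------
  w <- which(expo, arr.ind = TRUE)
  d_case <- c(w[, 1L], which(no_drug))
  d_name <- c(drugs$name[w[, 2L]], rep(FILLER_DRUG, sum(no_drug)))
  ordd <- order(d_case, method = "radix")
  d_case <- d_case[ordd]
  d_name <- d_name[ordd]
  nd <- tabulate(d_case, nbins = ncase)  # >= 1 for every case
  d_seq <- sequence(nd)
  roles <- sample(c("SS", "C", "I"), length(d_case), replace = TRUE,
                  prob = c(0.3, 0.6, 0.1))
  ps_pos <- cumsum(nd) - nd + floor(stats::runif(ncase) * nd) + 1L
  roles[ps_pos] <- "PS"
  drug_long <- data.frame(case = d_case, drug_seq = d_seq, role_cod = roles,
                          drugname = d_name, stringsAsFactors = FALSE)

  wr <- which(reac, arr.ind = TRUE)
  r_case <- c(wr[, 1L], which(no_reac))
  r_pt <- c(events$pt[wr[, 2L]], rep(FILLER_PT, sum(no_reac)))
  ordr <- order(r_case, method = "radix")
  reac_long <- data.frame(case = r_case[ordr], pt = r_pt[ordr],
                          stringsAsFactors = FALSE)

  outc_long <- data.frame(case = which(outc1 != "none"),
                          outc_cod = outc1[outc1 != "none"],
                          stringsAsFactors = FALSE)

  ## expand to versions -----------------------------------------------------
  ver_case <- rep(seq_len(ncase), n_versions)
  ver_no <- sequence(n_versions)
  pid <- caseid[ver_case] * 100L + ver_no
  # earlier versions carry an FDA date 30 days earlier; clinical content same
  ver_fda <- format(fda_date[ver_case] - 30L * (n_versions[ver_case] - ver_no),
                    "%Y%m%d")

  demo <- data.frame(
    primaryid = as.character(pid),
    caseid = as.character(caseid[ver_case]),
    caseversion = as.character(ver_no),
    fda_dt = ver_fda,
    event_dt = event_dt[ver_case],
    age = age_out[ver_case],
    age_cod = ifelse(nzchar(age_out[ver_case]), "YR", ""),
    sex = sex_out[ver_case],
    wt = wt_out[ver_case],
    wt_cod = ifelse(nzchar(wt_out[ver_case]), "KG", ""),
    occp_cod = occp_out[ver_case],
    reporter_country = country_out[ver_case],
    stringsAsFactors = FALSE)

  expand_child <- function(long) {
    nv <- n_versions[long$case]
    out <- long[rep(seq_len(nrow(long)), nv), , drop = FALSE]
    ver <- sequence(nv)
    out$primaryid <- as.character(caseid[out$case] * 100L + ver)
    out$caseid <- as.character(caseid[out$case])
    rownames(out) <- NULL
    out
  }
  drug_tab <- expand_child(drug_long)
  is_target_name <- drug_tab$drugname %in% config$signals$drug
  drug_df <- data.frame(
    primaryid = drug_tab$primaryid, caseid = drug_tab$caseid,
    drug_seq = as.character(drug_tab$drug_seq),
    role_cod = drug_tab$role_cod, drugname = drug_tab$drugname,
    prod_ai = drug_tab$drugname, stringsAsFactors = FALSE)
  reac_tab <- expand_child(reac_long)
  reac_df <- data.frame(primaryid = reac_tab$primaryid,
                        caseid = reac_tab$caseid, pt = reac_tab$pt,
                        stringsAsFactors = FALSE)
  outc_tab <- expand_child(outc_long)
  outc_df <- data.frame(primaryid = outc_tab$primaryid,
                        caseid = outc_tab$caseid,
                        outc_cod = outc_tab$outc_cod, stringsAsFactors = FALSE)
  ther_df <- data.frame(
    primaryid = drug_tab$primaryid, caseid = drug_tab$caseid,
    dsg_drug_seq = as.character(drug_tab$drug_seq),
    start_dt = start_dt_case[drug_tab$case],
    end_dt = "", stringsAsFactors = FALSE)
  indi_df <- data.frame(
    primaryid = drug_tab$primaryid, caseid = drug_tab$caseid,
    indi_drug_seq = as.character(drug_tab$drug_seq),
    indi_pt = ifelse(is_target_name, "Gastrointestinal stromal tumour",
                     "Product used for unknown indication"),
    stringsAsFactors = FALSE)

  ## ground truth -----------------------------------------------------------
  kept <- !deleted
  exposure_gt <- do.call(rbind, lapply(seq_len(K), function(k) {
    idx <- which(expo[, k] & kept)
    if (!length(idx)) return(NULL)
    data.frame(caseid = as.character(caseid[idx]), drug = drugs$name[k],
               stringsAsFactors = FALSE)
  }))
  signals_gt <- NULL
  if (!is.null(sig) && nrow(sig) > 0) {
    signals_gt <- sig
    signals_gt$p_conditional <- pmin(1, events$p[match(sig$pt, events$pt)] *
                                       sig$lambda)
    signals_gt$expected_a <- n * drugs$p[match(sig$drug, drugs$name)] *
      signals_gt$p_conditional
    signals_gt$observed_a <- vapply(seq_len(nrow(sig)), function(r) {
      k <- match(sig$drug[r], drugs$name)
      j <- match(sig$pt[r], events$pt)
      sum(expo[, k] & reac[, j] & kept)
    }, numeric(1))
  }
  gt <- list(
    n_reports = n,
    n_deleted = n_del,
    n_capped_probabilities = n_capped,
    cases = data.frame(
      caseid = as.character(caseid),
      canonical_primaryid = as.character(canonical_pid),
      n_versions = n_versions, deleted = deleted,
      sex = sex, country = country, outcome = outc1,
      onset_day = onset_day, onset_soc = onset_soc,
      n_drugs = ifelse(no_drug, 1L, rowSums(expo)),
      n_reactions = ifelse(no_reac, 1L, rowSums(reac)),
      stringsAsFactors = FALSE),
    exposure = exposure_gt,
    signals = signals_gt)

  list(tables = list(demo = demo, drug = drug_df, reac = reac_df,
                     outc = outc_df, ther = ther_df, indi = indi_df),
       deleted_caseids = as.character(caseid[deleted]),
       ground_truth = gt)
}

#' Generate a FAERS-format dataset on disk
#'
#' Writes `DEMO.txt`, `DRUG.txt`, `REAC.txt`, `OUTC.txt`, `THER.txt` and
#' `INDI.txt` in the "$"-delimited FAERS ASCII dialect (one header line,
#' empty string = missing), a deleted-case list (`deleted_cases.txt`, one
#' CASEID per line), a PT-to-SOC mapping (`meddra_map.tsv`) covering the
#' event catalog plus the filler PT, and the ground truth as
#' `ground_truth.json`. Identical config + seed gives byte-identical files.
#'
#' @param config a [sim_config()].
#' @param out_dir output directory (created if absent).
#' @return the ground-truth list, invisibly: planted signals with expected
#'   and realized `a` cell counts, per-case canonical PRIMARYIDs, true onset
#'   days, and per-drug exposure sets.
#' @export
generate_faers_dataset <- function(config, out_dir) {
  sim <- simulate_faers_tables(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(sim$tables)) {
    path <- file.path(out_dir, paste0(toupper(nm), ".txt"))
    tab <- sim$tables[[nm]]
    lines <- c(paste(names(tab), collapse = "$"),
               do.call(paste, c(unname(tab), sep = "$")))
    writeLines(lines, path)
  }
  writeLines(sim$deleted_caseids, file.path(out_dir, "deleted_cases.txt"))
  map_events <- rbind(config$events[c("pt", "soc")],
                      data.frame(pt = FILLER_PT, soc = FILLER_SOC,
                                 stringsAsFactors = FALSE))
  write_meddra_map(map_events, file.path(out_dir, "meddra_map.tsv"))
  jsonlite::write_json(sim$ground_truth,
                       file.path(out_dir, "ground_truth.json"),
                       dataframe = "columns", auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(sim$ground_truth)
}

#' Write a PT-to-SOC mapping file
#'
#' Two-column tab-separated file (`pt<TAB>soc`, with header) covering every
#' PT in the catalog; the interface stands in for licensed MedDRA content,
#' which is never bundled.
#'
#' @param event_catalog data.frame with columns `pt` and `soc`.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_meddra_map <- function(event_catalog, path) {
  if (!is.data.frame(event_catalog) ||
      !all(c("pt", "soc") %in% names(event_catalog)) ||
      nrow(event_catalog) < 1)
    stop("event_catalog must be a non-empty data.frame with columns pt, soc",
         call. = FALSE)
  map <- unique(event_catalog[c("pt", "soc")])
  if (anyDuplicated(map$pt))
    stop("duplicate PT mapped to conflicting SOCs: ",
         paste(unique(map$pt[duplicated(map$pt)]), collapse = ", "),
         call. = FALSE)
  write_tsv(map, path)
}
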