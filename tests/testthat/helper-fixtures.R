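# Shared fixtures: small simulation configs, in-memory linking, and a
# hand-rolled faers_cases builder for arithmetic checks.

# A minimal two-drug / two-PT world with one (optionally planted) pair.
pair_config <- function(n, p_drug, bg, lambda, seed,
                        duplicate_fraction = 0, deleted_fraction = 0) {
  sim_config(
    n_reports = n,
    drugs = data.frame(name = c("DRUGX", "OTHERA"), p = c(p_drug, 0.3),
                       stringsAsFactors = FALSE),
    events = data.frame(pt = c("PTY", "PTZ"),
                        soc = c("SOC one", "SOC two"),
                        p = c(bg, 0.15), stringsAsFactors = FALSE),
    signals = data.frame(drug = "DRUGX", pt = "PTY", lambda = lambda,
                         stringsAsFactors = FALSE),
    duplicate_fraction = duplicate_fraction,
    deleted_fraction = deleted_fraction,
    missing_rates = list(event_dt = 0, start_dt = 0, age = 0, wt = 0,
                         country = 0, occp = 0),
    partial_date_fraction = 0, seed = seed)
}

# Dedupe + link an in-memory simulation result.
link_sim <- function(sim) {
  demo <- dedupe_demo(sim$tables$demo, sim$deleted_caseids)
  link_cases(demo, sim$tables$drug, sim$tables$reac, sim$tables$outc,
             sim$tables$ther)
}

# MedDRA map covering a catalog (plus the generator's filler PT), loaded
# through the file interface so the round trip is exercised everywhere.
map_for <- function(events) {
  path <- tempfile(fileext = ".tsv")
  all_events <- rbind(events[c("pt", "soc")],
                      data.frame(pt = "Unspecified adverse event",
                                 soc = "General disorders and administration site conditions",
                                 stringsAsFactors = FALSE))
  write_meddra_map(all_events, path)
  load_meddra_map(path)
}

pair_map <- function() {
  map_for(data.frame(pt = c("PTY", "PTZ"), soc = c("SOC one", "SOC two"),
                     stringsAsFactors = FALSE))
}

all_roles <- function(keyword = "DRUGX") {
  cohort_config(keyword, roles = c("PS", "SS", "C", "I"))
}

# Build a faers_cases object directly from hand-specified tables.
manual_cases <- function(demo, drug = NULL, reac = NULL, outc = NULL,
                         ther = NULL) {
  empty <- function(cols) {
    out <- as.data.frame(matrix(character(0), ncol = length(cols)),
                         stringsAsFactors = FALSE)
    names(out) <- cols
    out
  }
  link_cases(demo,
             drug %||% empty(c("primaryid", "drug_seq", "role_cod",
                               "drugname", "prod_ai")),
             reac %||% empty(c("primaryid", "pt")),
             outc %||% empty(c("primaryid", "outc_cod")),
             ther %||% empty(c("primaryid", "dsg_drug_seq", "start_dt")))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# A demo row template with every column link_cases reads.
demo_frame <- function(primaryid, caseid = primaryid,
                       fda_dt = "20230101", event_dt = "", sex = "",
                       age = "", age_cod = "", wt = "",
                       reporter_country = "", occp_cod = "") {
  data.frame(primaryid = as.character(primaryid),
             caseid = as.character(caseid), fda_dt = fda_dt,
             event_dt = event_dt, sex = sex, age = age, age_cod = age_cod,
             wt = wt, reporter_country = reporter_country,
             occp_cod = occp_cod, stringsAsFactors = FALSE)
}

random_tables <- function(n, seed, min_cell = 1, max_cell = 1e6) {
  set.seed(seed)
  matrix(floor(stats::runif(4 * n, min_cell, max_cell + 1)), ncol = 4)
}
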