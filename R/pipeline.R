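#' Run configuration for the end-to-end pipeline
#'
#' Exactly one of `input_dir` (a directory of FAERS-format tables) or
#' `synthetic` (a [sim_config()], generated under `out_dir/data`) must be
#' given. The cohort block carries the drug keywords and role filter; the
#' MedDRA mapping defaults to `meddra_map.tsv` inside the input directory.
#'
#' @param input_dir directory with DEMO/DRUG/REAC/OUTC/THER tables, or NULL.
#' @param synthetic a [sim_config()], or NULL.
#' @param cohort a [cohort_config()].
#' @param meddra_map path to the PT-to-SOC mapping file; NULL = bundled with
#'   the input directory.
#' @param top_n rows kept in the ranked PT table.
#' @param rank_key ranking key, one of `"ebgm"`, `"n"`, `"ror"`.
#' @param soc_min_n exclusive minimum `n` for the SOC table.
#' @param onset_bin_edges lower bin edges in days for onset binning.
#' @param ic_method `"bate"` or `"mc"` (see [ic_stat()]).
#' @param seed integer seed recorded in the manifest and used for any
#'   stochastic step (synthetic generation, Monte-Carlo intervals).
#' @return an object of class `run_config`.
#' @export
run_config <- function(input_dir = NULL, synthetic = NULL,
                       cohort = cohort_config(c("Ripretinib", "QINLOCK",
                                                "DCC 2618")),
                       meddra_map = NULL, top_n = 40, rank_key = "ebgm",
                       soc_min_n = 100,
                       onset_bin_edges = default_onset_bins(),
                       ic_method = "bate", seed = 1L) {
  if (is.null(input_dir) == is.null(synthetic))
    stop_field("input_dir/synthetic", "exactly one must be provided")
  if (!inherits(cohort, "cohort_config"))
    stop_field("cohort", "must be a cohort_config")
  if (!is.numeric(top_n) || top_n < 0)
    stop_field("top_n", "must be a non-negative number")
  if (!is.numeric(soc_min_n) || soc_min_n < 0)
    stop_field("soc_min_n", "must be a non-negative number")
  structure(list(input_dir = input_dir, synthetic = synthetic,
                 cohort = cohort, meddra_map = meddra_map, top_n = top_n,
                 rank_key = rank_key, soc_min_n = soc_min_n,
                 onset_bin_edges = onset_bin_edges, ic_method = ic_method,
                 seed = as.integer(seed)), class = "run_config")
}

#' Run the full signal-detection pipeline
#'
#' Executes ingest -> deleted-case removal -> dedup -> link -> cohort ->
#' event counts -> disproportionality statistics and criteria ->
#' demographics -> time-to-onset, writing paper-style TSV tables and a run
#' manifest with row counts at every stage. Identical config + seed gives
#' identical outputs.
#'
#' Outputs written under `out_dir`: `demographics.tsv`,
#' `signals_pt.tsv` (ranked, top-N), `signals_pt_full.tsv`,
#' `signals_soc.tsv`, `onset_bins.tsv`, `onset_by_soc.tsv`,
#' and `manifest.json`.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created if absent).
#' @return invisibly, a list with every intermediate: `cases`, `cohort_ids`,
#'   `counts`, `signals_pt`, `signals_soc`, `demographics`, `onset`,
#'   `onset_summary`, `onset_by_soc`, `manifest`.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }

  data_dir <- config$input_dir
  ground_truth <- NULL
  if (!is.null(config$synthetic)) {
    data_dir <- file.path(out_dir, "data")
    ground_truth <- stage("simulate",
                          generate_faers_dataset(config$synthetic, data_dir))
  }

  demo_raw <- stage("ingest", read_faers_table(
    file.path(data_dir, "DEMO.txt"), "DEMO"))
  deleted <- character()
  del_path <- file.path(data_dir, "deleted_cases.txt")
  if (file.exists(del_path)) deleted <- read_deleted_cases(del_path)
  demo <- stage("dedupe", dedupe_demo(demo_raw, deleted))
  cases <- stage("link", link_cases(
    demo,
    read_faers_table(file.path(data_dir, "DRUG.txt"), "DRUG"),
    read_faers_table(file.path(data_dir, "REAC.txt"), "REAC"),
    read_faers_table(file.path(data_dir, "OUTC.txt"), "OUTC"),
    read_faers_table(file.path(data_dir, "THER.txt"), "THER")))

  map_path <- config$meddra_map %||% file.path(data_dir, "meddra_map.tsv")
  map <- stage("meddra", load_meddra_map(map_path))

  ids <- stage("cohort", match_target_reports(cases, config$cohort))
  counts <- stage("count", count_events(cases, ids, map))
  sig_pt <- stage("signals", compute_signals(counts, "PT",
                                             ic_method = config$ic_method))
  sig_soc <- stage("signals", compute_signals(counts, "SOC",
                                              ic_method = config$ic_method))
  ranked_pt <- rank_signals(sig_pt, top_n = config$top_n,
                            order_key = config$rank_key)
  ranked_soc <- rank_signals(sig_soc, order_key = config$rank_key,
                             soc_min_n = config$soc_min_n)

  demog <- stage("demographics", summarize_demographics(cases, ids))
  onset <- stage("onset", onset_days(cases, ids, config$cohort))
  osum <- onset_summary(onset$days, config$onset_bin_edges)
  orecs <- onset_records(cases, onset, map, config$onset_bin_edges)
  osoc <- onset_by_soc(orecs)

  manifest <- list(
    seed = config$seed,
    cohort = list(keywords = config$cohort$keywords,
                  roles = config$cohort$roles),
    stages = list(
      demo_rows_raw = nrow(demo_raw),
      demo_ragged_rows = attr(demo_raw, "n_ragged"),
      deleted_caseids = length(deleted),
      cases_after_dedup = nrow(demo),
      cohort_reports = length(ids),
      pt_terms = nrow(sig_pt),
      soc_terms = nrow(sig_soc),
      pt_signals_combined = sum(sig_pt$flag_combined),
      onset_included = osum$n,
      onset_exclusions = attr(onset, "exclusions")),
    anomalies = cases$anomalies,
    unmapped_pts = counts$n_unmapped)

  demo_tab <- do.call(rbind, lapply(
    c("sex", "weight", "age", "occupation", "country", "outcome"),
    function(nm) cbind(characteristic = rep(nm, nrow(demog[[nm]])),
                       demog[[nm]])))
  write_tsv(demo_tab, file.path(out_dir, "demographics.tsv"))
  write_tsv(format_signal_table(ranked_pt),
            file.path(out_dir, "signals_pt.tsv"))
  write_tsv(format_signal_table(sig_pt),
            file.path(out_dir, "signals_pt_full.tsv"))
  write_tsv(format_signal_table(ranked_soc),
            file.path(out_dir, "signals_soc.tsv"))
  write_tsv(osum$bins, file.path(out_dir, "onset_bins.tsv"))
  write_tsv(osoc, file.path(out_dir, "onset_by_soc.tsv"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(cases = cases, cohort_ids = ids, counts = counts,
                 signals_pt = sig_pt, signals_soc = sig_soc,
                 ranked_pt = ranked_pt, ranked_soc = ranked_soc,
                 demographics = demog, onset = onset, onset_summary = osum,
                 onset_by_soc = osoc, manifest = manifest,
                 ground_truth = ground_truth))
}

#' Format a signal table for display
#'
#' @param stats a signal table ([compute_signals()]).
#' @param digits decimal places for display; `NULL` keeps full precision.
#' @return a data.frame with numeric columns rounded when `digits` is set.
#' @export
format_signal_table <- function(stats, digits = NULL) {
  if (is.null(digits)) return(stats)
  num <- vapply(stats, is.numeric, logical(1)) & names(stats) != "n"
  stats[num] <- lapply(stats[num], round, digits = digits)
  stats
}

#' Load a run configuration from a YAML file
#'
#' Flat YAML mirror of [run_config()]: top-level keys `input_dir` or
#' `synthetic` (with `n_reports`, `seed`, optional `duplicate_fraction`,
#' `deleted_fraction`), `keywords`, `roles`, `meddra_map`, `top_n`,
#' `rank_key`, `soc_min_n`, `onset_bin_edges`, `ic_method`, `seed`.
#'
#' @param path YAML config path.
#' @return a [run_config()].
#' @export
load_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  synthetic <- NULL
  if (!is.null(y$synthetic)) {
    args <- y$synthetic
    synthetic <- do.call(sim_config, args)
  }
  run_config(
    input_dir = y$input_dir,
    synthetic = synthetic,
    cohort = cohort_config(keywords = unlist(y$keywords),
                           roles = unlist(y$roles %||% "PS")),
    meddra_map = y$meddra_map,
    top_n = y$top_n %||% 40,
    # YAML 1.1 reads a bare `n` as logical false; it means the count column
    rank_key = if (isFALSE(y$rank_key)) "n" else y$rank_key %||% "ebgm",
    soc_min_n = y$soc_min_n %||% 100,
    onset_bin_edges = unlist(y$onset_bin_edges %||% default_onset_bins()),
    ic_method = y$ic_method %||% "bate",
    seed = y$seed %||% 1L)
}
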