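test_that("demographic counts partition the cohort and percents sum to 100", {
  demo <- demo_frame(as.character(1:10),
                     sex = c("M", "M", "M", "F", "F", "", "M", "F", "M", "M"),
                     age = c("30", "70", "", "90", "50", "12", "70", "", "66", "80"),
                     age_cod = "YR",
                     wt = c("45", "80", "", "", "120", "60", "70", "", "", ""),
                     reporter_country = c(rep("US", 8), "FR", ""),
                     occp_cod = c("CN", "CN", "MD", "PH", "", "CN", "OT",
                                  "CN", "LW", "CN"))
  outc <- data.frame(primaryid = c("1", "1", "2", "3"),
                     outc_cod = c("HO", "DE", "HO", "OT"),
                     stringsAsFactors = FALSE)
  cases <- manual_cases(demo, outc = outc)
  s <- summarize_demographics(cases, as.character(1:10))
  expect_equal(s$n_reports, 10L)
  for (nm in c("sex", "weight", "age", "occupation", "country")) {
    expect_equal(sum(s[[nm]]$count), 10L, label = nm)
    expect_lt(abs(sum(s[[nm]]$percent) - 100), 0.15)
  }
  expect_equal(s$sex$count, c(6L, 3L, 1L))
  expect_equal(s$age$count[s$age$label == "<18"], 1L)
  expect_equal(s$age$count[s$age$label == ">85"], 1L)
  expect_equal(s$weight$count[s$weight$label == "50-100"], 3L)
  # LW grouped with consumers
  expect_equal(s$occupation$count[s$occupation$label == "Consumer"], 6L)
  # outcome entries: 4 coded + 7 reports without any = 11 entries
  expect_equal(s$n_outcome_entries, 11L)
  expect_equal(s$outcome$count[s$outcome$label == "Hospitalization"], 2L)
  expect_equal(s$outcome$percent[s$outcome$label == "Hospitalization"],
               round(100 * 2 / 11, 1))
})

test_that("demographics are invariant under case order and empty cohorts are zero", {
  sim <- simulate_faers_tables(pair_config(300, 0.3, 0.1, 1, seed = 14))
  cases <- link_sim(sim)
  ids <- cases$demo$primaryid
  s1 <- summarize_demographics(cases, ids)
  perm <- cases
  set.seed(1)
  perm$demo <- perm$demo[sample(nrow(perm$demo)), ]
  s2 <- summarize_demographics(perm, sample(ids))
  expect_equal(s1$sex, s2$sex)
  expect_equal(s1$outcome, s2$outcome)

  s0 <- summarize_demographics(cases, character())
  expect_equal(s0$n_reports, 0L)
  expect_true(all(s0$sex$count == 0L))
  expect_true(all(s0$sex$percent == 0))
})

test_that("onset intervals follow calendar arithmetic with tagged exclusions", {
  demo <- demo_frame(as.character(1:6),
                     event_dt = c("20230101", "20230410", "20221231",
                                  "202303", "", "20230301"))
  drug <- data.frame(primaryid = as.character(1:6), drug_seq = "1",
                     role_cod = "PS", drugname = "DRUGX", prod_ai = "DRUGX",
                     stringsAsFactors = FALSE)
  ther <- data.frame(primaryid = as.character(1:6), dsg_drug_seq = "1",
                     start_dt = c("20230101", "20230101", "20230101",
                                  "20230101", "20230101", "202301"),
                     stringsAsFactors = FALSE)
  cases <- manual_cases(demo, drug = drug, ther = ther)
  res <- onset_days(cases, as.character(1:6), cohort_config("DRUGX"))
  expect_equal(res$days[1:3], c(0L, 99L, NA))
  expect_equal(res$reason[3], "negative_interval")
  expect_equal(res$reason[4], "partial_date")
  expect_equal(res$reason[5], "missing_event_date")
  expect_equal(res$reason[6], "partial_date")
  excl <- attr(res, "exclusions")
  expect_equal(excl$partial_date, 2L)

  # translation invariance: shift both dates by 250 days
  shift <- function(x) format(as.Date(x, "%Y%m%d") + 250, "%Y%m%d")
  demo2 <- demo; demo2$event_dt[1:2] <- shift(demo$event_dt[1:2])
  ther2 <- ther; ther2$start_dt[1:2] <- shift(ther$start_dt[1:2])
  res2 <- onset_days(manual_cases(demo2, drug = drug, ther = ther2),
                     as.character(1:6), cohort_config("DRUGX"))
  expect_equal(res2$days[1:2], res$days[1:2])
})

test_that("earliest full-precision start among target therapies is used", {
  demo <- demo_frame("1", event_dt = "20230601")
  drug <- data.frame(primaryid = "1", drug_seq = c("1", "2"),
                     role_cod = c("PS", "C"),
                     drugname = c("DRUGX", "OTHERA"),
                     prod_ai = c("DRUGX", "OTHERA"), stringsAsFactors = FALSE)
  ther <- data.frame(primaryid = "1", dsg_drug_seq = c("1", "1", "2"),
                     start_dt = c("20230301", "20230101", "20220101"),
                     stringsAsFactors = FALSE)
  cases <- manual_cases(demo, drug = drug, ther = ther)
  res <- onset_days(cases, "1", cohort_config("DRUGX"))
  # the concomitant drug's earlier start must not be used
  expect_equal(res$days, 151L)
})

test_that("onset summary uses the (n+1)p quartile convention and month bins", {
  s <- onset_summary(c(27, 99, 245))
  expect_equal(s$median, 99)
  expect_equal(s$q1, 27)
  expect_equal(s$q3, 245)

  s2 <- onset_summary(c(rep(10, 165), rep(200, 452)))
  expect_equal(s2$n, 617L)
  first <- s2$bins[s2$bins$bin == "0-1 m", ]
  expect_equal(first$count, 165L)
  expect_equal(first$percent, 26.74)
  expect_lt(abs(sum(s2$bins$percent) - 100), 0.1)

  s3 <- onset_summary(rep(29, 12))
  expect_equal(s3$bins$percent[1], 100)

  s0 <- onset_summary(integer())
  expect_equal(s0$n, 0L)
  expect_true(is.na(s0$median))
})

test_that("custom bin edges produce edges + overflow bins", {
  lab <- onset_bins(c(0, 31, 61, 400), edges = c(0, 30, 60, 90))
  expect_equal(lab, c("0-1 m", "1-2 m", "2-3 m", ">3 m"))
})

test_that("per-SOC onset tables order by n and separate early from late SOCs", {
  rec <- data.frame(primaryid = as.character(1:5),
                    days = c(5, 10, 400, 2, 3),
                    pt = "x",
                    soc = c("A", "A", "B", "A", "A"),
                    bin = "0-1 m", stringsAsFactors = FALSE)
  by_soc <- onset_by_soc(rec)
  expect_equal(by_soc$soc, c("A", "B"))
  expect_equal(by_soc$n, c(4L, 1L))
  expect_equal(nrow(onset_by_soc(rec[0, ])), 0L)

  # generator oracle: a short-scale vs a long-scale Weibull SOC
  onset <- default_onset_model()
  onset$by_soc <- list(
    "SOC one" = list(mix = 1, shape_early = 1.2, scale_early = 5),
    "SOC two" = list(mix = 0, shape_late = 1.5, scale_late = 600))
  ordered_ok <- vapply(1:200, function(s) {
    cfg <- pair_config(200, 0.3, 0.45, 1, seed = s)
    cfg$onset <- onset
    sim <- simulate_faers_tables(cfg)
    gt <- sim$ground_truth$cases
    m1 <- stats::median(gt$onset_day[gt$onset_soc == "SOC one"])
    m2 <- stats::median(gt$onset_day[gt$onset_soc == "SOC two"])
    m1 < m2
  }, logical(1))
  expect_gt(mean(ordered_ok), 0.95)

  # and the full path reproduces the ordering on one realization
  cfg <- pair_config(600, 0.3, 0.45, 1, seed = 77)
  cfg$onset <- onset
  cfg$missing_rates$event_dt <- 0
  sim <- simulate_faers_tables(cfg)
  cases <- link_sim(sim)
  ids <- cases$demo$primaryid
  allcfg <- cohort_config(c("DRUGX", "OTHERA", "UNSPECIFIED MEDICATION"),
                          roles = c("PS", "SS", "C", "I"))
  od <- onset_days(cases, ids, allcfg)
  recs <- onset_records(cases, od, pair_map())
  tab <- onset_by_soc(recs)
  expect_lt(tab$median[tab$soc == "SOC one"],
            tab$median[tab$soc == "SOC two"])
})
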