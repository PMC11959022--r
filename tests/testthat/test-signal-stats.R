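# Reference table used throughout: a=10, b=90, c=100, d=9800 (N=10000).
ref <- contingency(10, 90, 100, 9800)

within_stats <- function(t2) {
  r <- ror_stat(t2); p <- prr_stat(t2); i <- ic_stat(t2); e <- ebgm_stat(t2)
  list(n = t2$a, ror_lo = r$lo, prr = p$est, chi2 = p$chi2, ic025 = i$lo,
       ebgm05 = e$lo)
}

test_that("2x2 construction from event counts is exact, degenerate cases included", {
  counts <- structure(list(
    pt = data.frame(term = c("X", "Solo"), n_target = c(10L, 1L),
                    n_total = c(110L, 1L), stringsAsFactors = FALSE),
    soc = data.frame(term = character(), n_target = integer(),
                     n_total = integer(), stringsAsFactors = FALSE),
    n_target_total = 100L, n_all = 10000L), class = "event_counts")
  t2 <- build_table(counts, "X")
  expect_equal(c(t2$a, t2$b, t2$c, t2$d), c(10, 90, 100, 9800))

  deg <- structure(list(
    pt = data.frame(term = "Only", n_target = 1L, n_total = 1L,
                    stringsAsFactors = FALSE),
    soc = counts$soc, n_target_total = 1L, n_all = 1L),
    class = "event_counts")
  td <- build_table(deg, "Only")
  expect_equal(c(td$a, td$b, td$c, td$d), c(1, 0, 0, 0))

  bad <- counts; bad$n_target_total <- 5L  # a > a+b: inconsistent
  expect_error(build_table(bad, "X"), "inconsistent")
  expect_error(build_table(counts, "Nope"), "not present")
})

test_that("the four statistics reproduce their closed forms on the reference table", {
  r <- ror_stat(ref)
  expect_equal(r$est, 98000 / 9000)
  expect_equal(r$lo, 5.503411, tolerance = 1e-6)
  expect_equal(r$hi, 21.544438, tolerance = 1e-6)

  p <- prr_stat(ref)
  expect_equal(p$est, 9.9)
  expect_equal(p$chi2, 73.545455, tolerance = 1e-6)
  expect_equal(p$lo, 5.328410, tolerance = 1e-6)
  expect_equal(p$hi, 18.393856, tolerance = 1e-6)

  i <- ic_stat(ref)
  expect_equal(i$est, log2(10 * 10000 / (110 * 100)))
  expect_equal(i$est, 3.184425, tolerance = 1e-6)
  expect_true(i$lo < i$est && i$est < i$hi)

  e <- ebgm_stat(ref)
  expect_equal(e$est, 10 * 10000 / (110 * 100))
  expect_equal(e$lo, 4.594685, tolerance = 1e-6)
})

test_that("a balanced table is the exact null for every statistic", {
  t0 <- contingency(25, 25, 25, 25)
  r <- ror_stat(t0); p <- prr_stat(t0); i <- ic_stat(t0); e <- ebgm_stat(t0)
  expect_equal(r$est, 1)
  expect_true(r$lo < 1 && r$hi > 1)
  expect_equal(p$est, 1)
  expect_equal(p$chi2, 0)
  expect_equal(i$est, 0)
  expect_equal(e$est, 1)
})

test_that("zero cells give flagged-undefined values, not corrected estimates", {
  tz <- contingency(1, 0, 5, 100)
  r <- ror_stat(tz)
  expect_false(r$defined)
  expect_equal(r$reason, "zero-cell")
  expect_true(is.na(r$est))
  p <- prr_stat(tz)
  expect_true(p$defined)
  expect_equal(p$est, 21)       # 1*105/(5*1)
  expect_true(is.finite(p$chi2))
  e <- ebgm_stat(tz)
  expect_equal(e$est, 1 * 106 / (1 * 6))
  expect_false(e$defined)       # interval needs all cells positive

  ta <- contingency(0, 10, 5, 100)
  expect_equal(ebgm_stat(ta)$est, 0)
  expect_true(ic_stat(ta)$defined)  # Bate posterior expectation at a = 0
  expect_lt(ic_stat(ta)$est, 0)
  expect_false(ic_stat(ta, method = "mc")$defined)
})

test_that("IC equals log2(EBGM) identically and the MC interval brackets it", {
  tabs <- random_tables(200, seed = 31)
  for (k in seq_len(nrow(tabs))) {
    t2 <- contingency(tabs[k, 1], tabs[k, 2], tabs[k, 3], tabs[k, 4])
    expect_equal(ic_stat(t2)$est, log2(ebgm_stat(t2)$est), tolerance = 1e-12)
  }
  set.seed(99)
  mc <- ic_stat(ref, method = "mc")
  expect_true(mc$lo < mc$est && mc$est < mc$hi)
  expect_equal(mc$est, ic_stat(ref)$est)
})

test_that("ROR is transpose-symmetric in b and c; PRR is not", {
  t1 <- contingency(12, 40, 90, 5000)
  t2 <- contingency(12, 90, 40, 5000)
  expect_equal(ror_stat(t1)$est, ror_stat(t2)$est)
  expect_false(isTRUE(all.equal(prr_stat(t1)$est, prr_stat(t2)$est)))
})

test_that("incrementing a strictly increases all four point estimates", {
  t1 <- contingency(10, 90, 100, 9800)
  t2 <- contingency(11, 90, 100, 9800)
  expect_gt(ror_stat(t2)$est, ror_stat(t1)$est)
  expect_gt(prr_stat(t2)$est, prr_stat(t1)$est)
  expect_gt(ic_stat(t2)$est, ic_stat(t1)$est)
  expect_gt(ebgm_stat(t2)$est, ebgm_stat(t1)$est)
})

test_that("chi-squared and ROR interval agree with independent oracles on 1000 tables", {
  tabs <- random_tables(1000, seed = 17)
  for (k in seq_len(nrow(tabs))) {
    a <- tabs[k, 1]; b <- tabs[k, 2]; cc <- tabs[k, 3]; d <- tabs[k, 4]
    t2 <- contingency(a, b, cc, d)
    p <- prr_stat(t2)
    oracle_chi2 <- suppressWarnings(stats::chisq.test(
      matrix(c(a, b, cc, d), 2, byrow = TRUE), correct = FALSE)$statistic)
    expect_equal(p$chi2, unname(oracle_chi2), tolerance = 1e-9)
    # textbook Wald log-odds-ratio interval
    r <- ror_stat(t2)
    lor <- log(a) + log(d) - log(b) - log(cc)
    se <- sqrt(1 / a + 1 / b + 1 / cc + 1 / d)
    expect_equal(r$est, exp(lor), tolerance = 1e-9)
    expect_equal(r$lo, exp(lor - stats::qnorm(0.975) * se), tolerance = 1e-9)
    expect_equal(r$hi, exp(lor + stats::qnorm(0.975) * se), tolerance = 1e-9)
  }
})

test_that("signal criteria apply the published boundaries exactly", {
  base <- list(n = 10, ror_lo = 2, prr = 3, chi2 = 10, ic025 = 0.5,
               ebgm05 = 3)
  expect_true(all(evaluate_criteria(base)))

  low_n <- base; low_n$n <- 2
  fl <- evaluate_criteria(low_n)
  expect_false(fl[["ror"]])
  expect_false(fl[["prr"]])
  expect_true(fl[["ic"]])       # IC criterion has no n threshold

  edge <- base; edge$ror_lo <- 1.0
  expect_false(evaluate_criteria(edge)[["ror"]])  # strict >

  prr_edge <- list(n = 3, ror_lo = 0.5, prr = 2.0, chi2 = 4.0, ic025 = -1,
                   ebgm05 = 1)
  fl <- evaluate_criteria(prr_edge)
  expect_true(fl[["prr"]])      # >= boundaries inclusive
  expect_true(fl[["combined"]])
  expect_false(fl[["all_four"]])

  undef <- base; undef$ror_lo <- NA_real_
  expect_false(evaluate_criteria(undef)[["ror"]])

  ic_edge <- base; ic_edge$ic025 <- 0
  expect_false(evaluate_criteria(ic_edge)[["ic"]])  # strict >
  eb_edge <- base; eb_edge$ebgm05 <- 2
  expect_false(evaluate_criteria(eb_edge)[["ebgm"]])
})

test_that("flagging is monotone in a", {
  counts_at <- function(a) contingency(a, 100 - a, 200, 9000)
  for (a in c(3, 10, 40)) {
    f1 <- evaluate_criteria(within_stats(counts_at(a)))
    f2 <- evaluate_criteria(within_stats(contingency(a + 1, 100 - a, 200, 9000)))
    for (nm in c("ror", "prr", "ic", "ebgm"))
      if (f1[[nm]]) expect_true(f2[[nm]], label = paste(nm, "a =", a))
  }
})

test_that("ranking orders by key with count and name tie-breaks", {
  stats <- data.frame(term = c("B", "A", "C", "D"), level = "PT",
                      n = c(10L, 7L, 10L, 2L), ebgm = c(3, 5, 3, 5),
                      ror = c(1, 2, 3, 4), stringsAsFactors = FALSE)
  out <- rank_signals(stats, soc_min_n = 0)
  expect_equal(out$term, c("A", "D", "B", "C"))  # ebgm desc, n desc, name
  expect_equal(rank_signals(stats, top_n = 0)$term, character(0))
  expect_equal(rank_signals(stats, order_key = "n")$term[1], "B")

  soc <- data.frame(term = c("S1", "S2"), level = "SOC", n = c(150L, 50L),
                    ebgm = c(1, 9), ror = c(1, 9), stringsAsFactors = FALSE)
  expect_equal(rank_signals(soc)$term, "S1")  # n > 100 filter
})

test_that("planted strong signal ranks first among nulls", {
  sim <- simulate_faers_tables(pair_config(3000, 0.25, 0.05, 10, seed = 13))
  cases <- link_sim(sim)
  ids <- match_target_reports(cases, all_roles())
  counts <- count_events(cases, ids, pair_map())
  sig <- compute_signals(counts, "PT")
  expect_gte(sim$ground_truth$signals$observed_a, 30)
  expect_equal(rank_signals(sig)$term[1], "PTY")
})

test_that("table reconstruction inverts the printed statistics", {
  t2 <- reconstruct_table(10, 10000, 98000 / 9000, 9.9)
  expect_equal(c(t2$b, t2$c, t2$d), c(90, 100, 9800), tolerance = 1e-8)

  tabs <- random_tables(50, seed = 23, min_cell = 5, max_cell = 5000)
  for (k in seq_len(nrow(tabs))) {
    a <- tabs[k, 1]; b <- tabs[k, 2]; cc <- tabs[k, 3]; d <- tabs[k, 4]
    t0 <- contingency(a, b, cc, d)
    ror <- ror_stat(t0)$est
    prr <- prr_stat(t0)$est
    if (!is.finite(ror) || !is.finite(prr) || ror <= prr) next
    got <- reconstruct_table(a, t0$N, ror, prr)
    expect_equal(c(got$b, got$c, got$d), c(b, cc, d), tolerance = 1e-6)
  }
  expect_error(reconstruct_table(10, 100, 1e-8, 1e9), "feasible|positive")
})
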