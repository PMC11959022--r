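#' Contingency table for a drug-event pair
#'
#' The 2x2 table underlying every disproportionality statistic:
#' `a` = reports with both the target drug and the term, `b` = target-drug
#' reports with other terms, `c` = other-drug reports with the term,
#' `d` = reports with neither; `N = a + b + c + d`.
#'
#' @param a,b,c,d non-negative counts.
#' @return an object of class `contingency`.
#' @export
contingency <- function(a, b, c, d) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(!is.finite(cells)) || any(cells < 0))
    stop("contingency cells must be non-negative finite numbers", call. = FALSE)
  if (sum(cells) < 1) stop("contingency table must have N >= 1", call. = FALSE)
  # store as doubles: cell products (chi-squared denominator) overflow
  # 32-bit integers even at modest database sizes
  a <- as.numeric(a); b <- as.numeric(b)
  c <- as.numeric(c); d <- as.numeric(d)
  structure(list(a = a, b = b, c = c, d = d, N = a + b + c + d),
            class = "contingency")
}

#' @export
print.contingency <- function(x, ...) {
  cat(sprintf("2x2 table: a=%g b=%g c=%g d=%g (N=%g)\n",
              x$a, x$b, x$c, x$d, x$N))
  invisible(x)
}

#' Build the 2x2 table for a term from event counts
#'
#' `a = n_target(term)`, `b = n_target_total - a`, `c = n_total(term) - a`,
#' `d = N - a - b - c`; a negative cell means the counts are inconsistent
#' and is a hard error.
#'
#' @param counts an `event_counts` object ([count_events()]).
#' @param term PT or SOC name, as recorded in `counts`.
#' @param level `"PT"` or `"SOC"`.
#' @return a [contingency()] table.
#' @export
build_table <- function(counts, term, level = c("PT", "SOC")) {
  level <- match.arg(level)
  tab <- if (level == "PT") counts$pt else counts$soc
  i <- match(term, tab$term)
  if (is.na(i)) stop("term not present in counts: ", term, call. = FALSE)
  a <- tab$n_target[i]
  b <- counts$n_target_total - a
  cc <- tab$n_total[i] - a
  d <- counts$n_all - a - b - cc
  if (min(a, b, cc, d) < 0)
    stop(sprintf("inconsistent counts for '%s': a=%g b=%g c=%g d=%g",
                 term, a, b, cc, d), call. = FALSE)
  contingency(a, b, cc, d)
}

Z95 <- stats::qnorm(0.975)

undefined_stat <- function(fields, reason) {
  out <- as.list(rep(NA_real_, length(fields)))
  names(out) <- fields
  out$defined <- FALSE
  out$reason <- reason
  out
}

#' Reporting odds ratio with 95% Wald interval
#'
#' `ROR = ad/(bc)` with the log-scale interval
#' `exp(ln ROR +/- 1.96 * sqrt(1/a + 1/b + 1/c + 1/d))`. No continuity
#' correction is applied: a zero cell yields an undefined estimate tagged
#' `"zero-cell"` rather than a corrected value.
#'
#' @param t a [contingency()] table.
#' @return list with `est`, `lo`, `hi`, `defined`, `reason`.
#' @export
ror_stat <- function(t) {
  if (min(t$a, t$b, t$c, t$d) == 0)
    return(undefined_stat(c("est", "lo", "hi"), "zero-cell"))
  est <- (t$a * t$d) / (t$b * t$c)
  se <- sqrt(1 / t$a + 1 / t$b + 1 / t$c + 1 / t$d)
  list(est = est, lo = exp(log(est) - Z95 * se), hi = exp(log(est) + Z95 * se),
       defined = TRUE, reason = NA_character_)
}

#' Proportional reporting ratio, 95% interval and Pearson chi-squared
#'
#' `PRR = a(c+d) / (c(a+b))`; the interval uses the conventional log-PRR
#' standard error `sqrt(1/a - 1/(a+b) + 1/c - 1/(c+d))`; the chi-squared
#' statistic is the uncorrected Pearson form
#' `(ad - bc)^2 N / ((a+b)(c+d)(a+c)(b+d))` (no Yates correction).
#' The PRR itself requires only `a > 0` and `c > 0`; the chi-squared is
#' defined whenever all four margins are positive.
#'
#' @param t a [contingency()] table.
#' @return list with `est`, `lo`, `hi`, `chi2`, `defined`, `reason`.
#' @export
prr_stat <- function(t) {
  a <- t$a; b <- t$b; cc <- t$c; d <- t$d; N <- t$N
  chi2 <- {
    den <- (a + b) * (cc + d) * (a + cc) * (b + d)
    if (den > 0) (a * d - b * cc)^2 * N / den else NA_real_
  }
  if (a == 0 || cc == 0) {
    out <- undefined_stat(c("est", "lo", "hi"), "zero-cell")
    out$chi2 <- chi2
    return(out)
  }
  est <- a * (cc + d) / (cc * (a + b))
  se2 <- 1 / a - 1 / (a + b) + 1 / cc - 1 / (cc + d)
  se <- sqrt(max(se2, 0))
  list(est = est, lo = exp(log(est) - Z95 * se), hi = exp(log(est) + Z95 * se),
       chi2 = chi2, defined = TRUE, reason = NA_character_)
}

# Bate et al. (1998) closed-form posterior moments of the information
# component, with the standard default priors gamma11 = 1, alpha1 = beta1 = 1,
# alpha = beta = 2 and gamma chosen so the prior IC expectation is 0.
bcpnn_moments <- function(a, b, cc, d) {
  N <- a + b + cc + d
  a1 <- 1; b1 <- 1; al <- 2; be <- 2; g11 <- 1
  n1. <- a + b
  n.1 <- a + cc
  gam <- g11 * (N + al) * (N + be) / ((n1. + a1) * (n.1 + b1))
  eic <- log2((a + g11) * (N + al) * (N + be) /
                ((N + gam) * (n1. + a1) * (n.1 + b1)))
  vic <- (1 / log(2)^2) * (
    (N - a + gam - g11) / ((a + g11) * (1 + N + gam)) +
    (N - n1. + al - a1) / ((n1. + a1) * (1 + N + al)) +
    (N - n.1 + be - b1) / ((n.1 + b1) * (1 + N + be)))
  list(e = eic, v = vic)
}

#' BCPNN information component with 95% interval
#'
#' The point estimate is the observed information component
#' `IC = log2(aN / ((a+b)(a+c)))` — identically `log2(EBGM)`, with which it
#' shares its formula core. The interval is `IC +/- 2 sqrt(V(IC))` where
#' `V(IC)` is the Bate et al. (1998) closed-form posterior variance with
#' the standard default priors; `method = "mc"` replaces it by Monte-Carlo
#' quantiles of the posterior of `log2(p11/(p1. p.1))` under the same
#' priors. With `a = 0` the observed IC diverges; the Bayesian posterior
#' expectation is then used as the point estimate under `method = "bate"`,
#' and the estimate is undefined under `method = "mc"`.
#'
#' @param t a [contingency()] table.
#' @param method `"bate"` (closed form, default) or `"mc"`.
#' @param mc_samples posterior draws for `method = "mc"`.
#' @return list with `est`, `lo`, `hi`, `defined`, `reason`.
#' @export
ic_stat <- function(t, method = c("bate", "mc"), mc_samples = 20000) {
  method <- match.arg(method)
  a <- t$a; b <- t$b; cc <- t$c; d <- t$d; N <- t$N
  n1. <- a + b
  n.1 <- a + cc
  if (n1. == 0 || n.1 == 0)
    return(undefined_stat(c("est", "lo", "hi"), "zero-margin"))
  if (method == "mc") {
    if (a == 0) return(undefined_stat(c("est", "lo", "hi"), "zero-cell"))
    p11 <- stats::rbeta(mc_samples, 1 + a, 1 + N - a)
    p1. <- stats::rbeta(mc_samples, 1 + n1., 1 + N - n1.)
    p.1 <- stats::rbeta(mc_samples, 1 + n.1, 1 + N - n.1)
    draws <- log2(p11 / (p1. * p.1))
    q <- stats::quantile(draws, c(0.025, 0.975), names = FALSE, type = 6)
    return(list(est = log2(a * N / (n1. * n.1)), lo = q[1], hi = q[2],
                defined = TRUE, reason = NA_character_))
  }
  mom <- bcpnn_moments(a, b, cc, d)
  est <- if (a > 0) log2(a * N / (n1. * n.1)) else mom$e
  half <- 2 * sqrt(mom$v)
  list(est = est, lo = est - half, hi = est + half,
       defined = TRUE, reason = if (a > 0) NA_character_ else "zero-cell-posterior")
}

#' Closed-form empirical Bayes geometric mean with 95% interval
#'
#' `EBGM = aN / ((a+c)(a+b))` — the observed relative reporting ratio — with
#' the log-scale interval `exp(ln EBGM +/- 1.96 sqrt(1/a + 1/b + 1/c + 1/d))`.
#' This is the closed (non-shrunk) form; full gamma-Poisson hyperparameter
#' fitting is deliberately out of scope. With `a = 0` the estimate is 0 and
#' the interval undefined.
#'
#' @param t a [contingency()] table.
#' @return list with `est`, `lo`, `hi`, `defined`, `reason`.
#' @export
ebgm_stat <- function(t) {
  a <- t$a; b <- t$b; cc <- t$c; d <- t$d; N <- t$N
  n1. <- a + b
  n.1 <- a + cc
  if (n1. == 0 || n.1 == 0)
    return(undefined_stat(c("est", "lo", "hi"), "zero-margin"))
  if (a == 0)
    return(list(est = 0, lo = NA_real_, hi = NA_real_, defined = FALSE,
                reason = "zero-cell"))
  est <- a * N / (n1. * n.1)
  if (min(b, cc, d) == 0) {
    return(list(est = est, lo = NA_real_, hi = NA_real_, defined = FALSE,
                reason = "zero-cell"))
  }
  se <- sqrt(1 / a + 1 / b + 1 / cc + 1 / d)
  list(est = est, lo = exp(log(est) - Z95 * se), hi = exp(log(est) + Z95 * se),
       defined = TRUE, reason = NA_character_)
}

#' Signal criteria of the four algorithms
#'
#' ROR: lower 95% bound strictly > 1 and n >= 3. PRR: PRR >= 2, chi2 >= 4
#' and n >= 3 (boundaries inclusive). BCPNN: IC025 strictly > 0.
#' MGPS: EBGM05 strictly > 2. An undefined statistic never flags.
#' `combined` is "at least one algorithm positive"; `all_four` is the
#' stricter conjunction.
#'
#' @param s one row of a signal table ([compute_signals()]) or a list with
#'   fields `n`, `ror_lo`, `prr`, `chi2`, `ic025`, `ebgm05`.
#' @return named logical vector: `ror`, `prr`, `ic`, `ebgm`, `combined`,
#'   `all_four`.
#' @export
evaluate_criteria <- function(s) {
  val <- function(x) !is.null(x) && length(x) == 1 && is.finite(x)
  ror_f <- val(s$ror_lo) && val(s$n) && s$ror_lo > 1 && s$n >= 3
  prr_f <- val(s$prr) && val(s$chi2) && val(s$n) &&
    s$prr >= 2 && s$chi2 >= 4 && s$n >= 3
  ic_f <- val(s$ic025) && s$ic025 > 0
  ebgm_f <- val(s$ebgm05) && s$ebgm05 > 2
  c(ror = ror_f, prr = prr_f, ic = ic_f, ebgm = ebgm_f,
    combined = ror_f || prr_f || ic_f || ebgm_f,
    all_four = ror_f && prr_f && ic_f && ebgm_f)
}

#' Compute the full signal table at one level
#'
#' Builds the 2x2 table for every term in `counts` at the requested level
#' and computes all four statistics, intervals, chi-squared and the
#' per-algorithm signal flags.
#'
#' @param counts an `event_counts` object.
#' @param level `"PT"` or `"SOC"`.
#' @param ic_method passed to [ic_stat()].
#' @return data.frame with one row per term: `term`, `level`, `n`, `ror`,
#'   `ror_lo`, `ror_hi`, `prr`, `prr_lo`, `prr_hi`, `chi2`, `ic`, `ic025`,
#'   `ic975`, `ebgm`, `ebgm05`, `ebgm95`, logical flag columns
#'   (`flag_ror`, `flag_prr`, `flag_ic`, `flag_ebgm`, `flag_combined`,
#'   `flag_all_four`) and `undefined_reason`.
#' @export
compute_signals <- function(counts, level = c("PT", "SOC"),
                            ic_method = "bate") {
  level <- match.arg(level)
  tab <- if (level == "PT") counts$pt else counts$soc
  rows <- lapply(tab$term, function(term) {
    t2 <- build_table(counts, term, level)
    r <- ror_stat(t2)
    p <- prr_stat(t2)
    i <- ic_stat(t2, method = ic_method)
    e <- ebgm_stat(t2)
    reasons <- stats::na.omit(c(r$reason, p$reason, i$reason, e$reason))
    row <- data.frame(
      term = term, level = level, n = t2$a,
      ror = r$est, ror_lo = r$lo, ror_hi = r$hi,
      prr = p$est, prr_lo = p$lo, prr_hi = p$hi, chi2 = p$chi2,
      ic = i$est, ic025 = i$lo, ic975 = i$hi,
      ebgm = e$est, ebgm05 = e$lo, ebgm95 = e$hi,
      undefined_reason = if (length(reasons)) paste(unique(reasons),
                                                    collapse = ";")
                         else NA_character_,
      stringsAsFactors = FALSE)
    fl <- evaluate_criteria(list(n = row$n, ror_lo = row$ror_lo,
                                 prr = row$prr, chi2 = row$chi2,
                                 ic025 = row$ic025, ebgm05 = row$ebgm05))
    row$flag_ror <- fl[["ror"]]; row$flag_prr <- fl[["prr"]]
    row$flag_ic <- fl[["ic"]]; row$flag_ebgm <- fl[["ebgm"]]
    row$flag_combined <- fl[["combined"]]
    row$flag_all_four <- fl[["all_four"]]
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Rank a signal table
#'
#' Sorts descending by `order_key` (default EBGM), breaking ties by `n`
#' (larger first) then term name; optionally keeps the top `top_n` rows
#' and, at SOC level, drops terms with `n <= soc_min_n` first (the
#' convention used for "significant SOC" tables).
#'
#' @param stats a signal table from [compute_signals()].
#' @param top_n rows to keep; `Inf` keeps all; `<= 0` returns an empty table.
#' @param order_key one of `"ebgm"`, `"n"`, `"ror"`.
#' @param soc_min_n when the table is SOC-level, minimum `n` (exclusive);
#'   default 100.
#' @return the ranked (and possibly truncated) data.frame.
#' @export
rank_signals <- function(stats, top_n = Inf, order_key = c("ebgm", "n", "ror"),
                         soc_min_n = 100) {
  order_key <- match.arg(order_key)
  if (top_n <= 0) return(stats[0, , drop = FALSE])
  if (nrow(stats) && all(stats$level == "SOC"))
    stats <- stats[stats$n > soc_min_n, , drop = FALSE]
  key <- stats[[order_key]]
  key[!is.finite(key)] <- -Inf
  ord <- order(-key, -stats$n, stats$term, method = "radix")
  out <- stats[ord, , drop = FALSE]
  if (is.finite(top_n)) out <- utils::head(out, top_n)
  rownames(out) <- NULL
  out
}

#' Reconstruct a 2x2 table from its margins and printed statistics
#'
#' Given `a`, `N` and target ROR and PRR values, solves for the real-valued
#' cells `b`, `c`, `d = N - a - b - c` reproducing both statistics. Used to
#' recover full tables from published signal tables, which print `a`, `N`,
#' ROR and PRR but not `b` and `c`. The PRR equation gives `c` in closed
#' form for any `b`; the ROR equation is then solved for `b` by
#' root-finding, and the solution is unique in the feasible region where
#' `b, c` are small relative to `N`.
#'
#' @param a reports with drug and event (>= 1).
#' @param N database size (> a).
#' @param ror_target,prr_target target statistic values; must satisfy
#'   `ror_target > prr_target > 0` (the ROR always exceeds the PRR on the
#'   same table when d/c > (c+d-c)/..., i.e. for a genuine 2x2).
#' @param tol relative tolerance on both reproduced statistics.
#' @return a [contingency()] table with real-valued cells.
#' @export
reconstruct_table <- function(a, N, ror_target, prr_target, tol = 1e-10) {
  if (a < 1 || N <= a) stop("need a >= 1 and N > a", call. = FALSE)
  if (!(ror_target > 0 && prr_target > 0))
    stop("targets must be positive", call. = FALSE)
  c_of_b <- function(b) a * (N - a - b) / (prr_target * (a + b))
  resid <- function(b) {
    cc <- c_of_b(b)
    d <- N - a - b - cc
    if (cc <= 0 || d <= 0) return(NA_real_)
    log(a * d / (b * cc)) - log(ror_target)
  }
  lo <- 1e-9
  hi <- N - a - 1e-9
  # shrink the bracket to where c and d stay positive
  f_lo <- resid(lo)
  f_hi <- resid(hi)
  while (is.na(f_hi) && hi > 1) { hi <- hi / 2; f_hi <- resid(hi) }
  if (is.na(f_lo) || is.na(f_hi) || f_lo * f_hi > 0)
    stop(sprintf(
      "no feasible table for a=%g N=%g ROR=%g PRR=%g (residuals %.3g, %.3g)",
      a, N, ror_target, prr_target, f_lo, f_hi), call. = FALSE)
  b <- stats::uniroot(resid, c(lo, hi), tol = 1e-12)$root
  cc <- c_of_b(b)
  d <- N - a - b - cc
  t2 <- contingency(a, b, cc, d)
  got_ror <- ror_stat(t2)$est
  got_prr <- prr_stat(t2)$est
  if (abs(got_ror / ror_target - 1) > tol || abs(got_prr / prr_target - 1) > tol)
    stop(sprintf("reconstruction residuals exceed tolerance: ROR %.3g, PRR %.3g",
                 got_ror / ror_target - 1, got_prr / prr_target - 1),
         call. = FALSE)
  t2
}
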