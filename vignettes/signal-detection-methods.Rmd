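---
title: "Disproportionality methods in faersignal"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disproportionality methods in faersignal}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(faersignal)
```

## The problem

Spontaneous reporting systems such as FAERS collect adverse-event (AE)
reports without a denominator: there is no exposure count, only reports.
Disproportionality analysis sidesteps this by asking whether an event is
reported *relatively* more often with a target drug than with everything
else in the database. For each drug–event pair a 2×2 table is formed over
distinct reports —

|              | event       | other events |
|--------------|-------------|--------------|
| target drug  | a           | b            |
| other drugs  | c           | d            |

— and a measure of association is computed. Because reporting is
voluntary and biased, these are *signals* of disproportionate reporting,
not incidence estimates and not causal claims; every statistic here should
be read that way.

## Statistics and intervals

`faersignal` implements the four measures conventionally used together,
exactly in their printed closed forms:

* **ROR** `= ad/(bc)`, with the Wald interval on the log scale,
  standard error `sqrt(1/a + 1/b + 1/c + 1/d)`. Undefined when any cell
  is zero; we deliberately apply **no Haldane/continuity correction**,
  because a corrected estimate silently changes signal flags — an
  undefined value with a `zero-cell` tag is more honest.
* **PRR** `= a(c+d)/(c(a+b))`, paired with the **uncorrected** Pearson
  chi-squared `(ad − bc)² N / ((a+b)(c+d)(a+c)(b+d))` (no Yates
  correction). The PRR interval uses the conventional log-PRR standard
  error `sqrt(1/a − 1/(a+b) + 1/c − 1/(c+d))`; published signal tables
  often print PRR intervals without stating a formula, and this is the
  standard pharmacovigilance choice, documented here as an assumption.
* **BCPNN information component** `IC = log2(aN/((a+b)(a+c)))`. The
  interval is `IC ± 2·sqrt(V(IC))` with `V(IC)` the closed-form posterior
  variance of Bate et al. (1998) under the customary priors
  (`gamma11 = 1`, `alpha1 = beta1 = 1`, `alpha = beta = 2`, `gamma` tuned
  so the prior IC expectation is zero). `ic_stat(method = "mc")` instead
  takes Monte-Carlo quantiles of `log2(p11/(p1·p·1))` under independent
  Beta posteriors with the same priors; the closed form is the default
  because it is deterministic and the canonical published choice. At
  `a = 0` the observed IC diverges and the Bayesian posterior expectation
  is reported instead (closed form only).
* **EBGM**, implemented as the closed form `aN/((a+b)(a+c))` with a
  log-scale Wald interval. Full MGPS empirical-Bayes gamma-Poisson
  shrinkage is intentionally out of scope: the closed form is what most
  published signal tables actually tabulate at moderate counts, and a
  shrinkage estimator can be plugged in behind the same interface later.
  Note `IC = log2(EBGM)` *identically* — the two statistics share their
  formula core, and the package exploits this as an internal consistency
  check.

Signal criteria follow the published conventions exactly: ROR lower bound
**strictly** greater than 1 with `n ≥ 3`; `PRR ≥ 2` **and** `χ² ≥ 4`
(boundaries inclusive) with `n ≥ 3`; `IC025 > 0`; `EBGM05 > 2`. The
combined flag defaults to *any algorithm positive* — the common reading of
"at least one positive indicator" — with a stricter all-four flag reported
alongside, since the two readings can differ materially.

A caveat on published interval columns: printed IC025 values in signal
tables of this kind often sit at a near-constant offset below IC across
terms with very different counts, and printed EBGM05 values can be
inconsistent with any stated interval formula. No count-dependent variance
reproduces such columns, so the package validates its IC and EBGM
*point* estimates and its own interval definitions, not third-party
interval printouts.

## Counting unit and table construction

All counts are over **distinct deduplicated reports**: a report mentioning
a PT twice counts once, and a report with two PTs of the same SOC counts
once at SOC level. This is the only unit consistent with published
demographic denominators and per-PT "case report" columns. `build_table()`
derives `b`, `c`, `d` from the margins, and errors on negative cells
rather than clamping.

`reconstruct_table()` inverts this construction: given the `(a, N, ROR,
PRR)` quadruple that signal tables print, it solves the PRR equation for
`c` in closed form given `b` and root-finds `b` on the ROR equation
(unique in the feasible region where `b, c ≪ N`), recovering the full
table to relative precision 1e-10. This makes printed interval bounds
reproducible even though `b` and `c` are never published.

## Ingestion rules

* **Deduplication** (the database distributes every revision of a case):
  per CASEID keep the row with the latest FDA date, ties broken by the
  largest numeric PRIMARYID; deleted-case lists are applied afterwards.
  Published analyses rarely state their rule; this is the
  FDA-recommended practice and is deterministic, idempotent and
  order-stable (output sorted by CASEID).
* **Dates** are digit strings at day (8), month (6) or year (4)
  precision; dedup comparisons use lexicographic order on the padded
  string, valid for YYYYMMDD prefixes.
* **Age** is normalized to years (decade ×10, month ÷12, week ÷52.18,
  day ÷365.25); unparseable values become missing. **Weight** is taken as
  kilograms with values above 400 kg set missing — a crude, logged
  outlier guard.
* Ragged rows, orphan child rows (PRIMARYIDs absent from the deduplicated
  DEMO), empty PTs and unknown outcome codes are dropped and tallied,
  never fatal; the pipeline manifest reports every tally.

## Time to onset

Onset is `event date − earliest full-precision therapy start date` among
the therapy rows of target-drug mentions. Reports with missing event or
start dates, only partial-precision dates, or negative intervals are
excluded with tagged reasons — imputing partial dates would manufacture
onset mass at month boundaries. Quartiles (median, IQR) use the `(n+1)p`
linear-interpolation convention (R `quantile` type 6); the convention is
fixed and documented because three-point examples make the choice visible,
and determinism matters more than any particular convention. Bins are
30-day months: six monthly bins, one coarse 6–12-month bin, and an
overflow bin — matching how onset histograms in this literature are drawn.

## The synthetic generator

`sim_config()` + `generate_faers_dataset()` emulate the structural
features the pipeline must survive: multi-table cases keyed by
PRIMARYID/CASEID, duplicate case versions (identical clinical content,
earlier FDA date, distinct PRIMARYID — so dedup ground truth is
unambiguous), deleted-case lists (generated as *extra* cases so removal
recovers exactly `n_reports`), suspect/concomitant roles, Zipf-like
background PT frequencies, categorical demographics, outcome codes,
partial dates and per-field missingness.

Reports are generated case-first — demographics, then drug exposures,
then reactions with planted multipliers — so expected cell counts are
analytic: for a planted `(drug, PT, λ)` pair the conditional reporting
probability given exposure is exactly `min(1, λ·background)` (capping is
counted and reported). Two filler entities keep this exact: a report that
draws no catalog drug gets `UNSPECIFIED MEDICATION` and one with no
catalog reaction gets `Unspecified adverse event`; redrawing instead would
bias conditionals. Onset days come from a two-component Weibull mixture
(default: 45% early, shape 0.9 / scale 35 days; 55% late, shape 1.6 /
scale 320 days), chosen to produce the early first-month peak and late
rise reported for kinase-inhibitor AEs; per-SOC overrides allow planting
early- vs late-onset organ classes. The default catalogs and demographic
distributions mirror the marginal proportions of a real ripretinib
cohort (male 53.9%, US 92.9%, heavy weight/age missingness, etc.) so that
summaries look realistic at a glance.

What the generator does **not** emulate: real FAERS marginal frequencies
and drug dictionaries, narrative fields, correlated drug co-exposure,
reporting-date seasonality, or LLT-level coding. Passing tests therefore
demonstrate correctness of the *mechanics* (counting, dedup, statistics,
exclusion rules) under a known model — not robustness to every real-world
coding pathology.

## Calibration evidence and simulation sizes

The test suite validates the statistics against independent oracles
(uncorrected Pearson chi-squared from `chisq.test`, textbook log-odds
intervals) on 1,000 random tables, and calibrates the generator +
pipeline end to end:

* **Null calibration**: 200 replicates of a 2,000-report database with
  `λ = 1` (drug marginal 0.3, background 0.25, expected `a ≈ 150`); the
  95% ROR interval covers 1 in ≈95% of replicates (accepted band 91–98%,
  the binomial tolerance at 200 replicates).
* **Signal recovery**: 120 replicates of a 20,000-report database with
  `λ = 5` on a background of 0.004 (expected `a = 120`); the replicate
  mean ROR falls within 15% of λ. The background is kept small so that
  the true odds ratio (5.08) sits close to λ — at large backgrounds the
  odds ratio and the rate multiplier diverge by construction, which is a
  property of the measure, not an estimation error.

These sizes were chosen once, for binomial stability of the check, and
are stated here as the package's simulation design.

## Known limitations

* The closed-form EBGM does not shrink small counts; rare-event EBGM
  values are noisier than true MGPS output.
* Keyword cohorts are substring-based by design (fuzzy matching would
  change counts silently); misspelled drug names in real data are missed.
* No stratified (age/sex) disproportionality, no multiple-testing
  correction (matching common practice in this literature), no LLT→PT
  mapping (licensed MedDRA content is never bundled — only a PT→SOC
  mapping-file interface).
* Multi-drug interaction and concomitant-medication confounding are out
  of scope; role filtering is the only exposure refinement offered.
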