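Package: faersignal
Title: Disproportionality Signal Detection for FAERS-Format Spontaneous Reports
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: A pharmacovigilance pipeline for spontaneous adverse-event
    reports in the FDA Adverse Event Reporting System (FAERS) quarterly
    ASCII format: table ingestion, deleted-case removal and case-version
    deduplication, keyword-based suspect-drug cohort building, MedDRA
    PT/SOC aggregation, four disproportionality statistics (reporting
    odds ratio, proportional reporting ratio with Pearson chi-squared,
    Bayesian confidence propagation neural network information component,
    and the closed-form empirical Bayes geometric mean) with confidence
    intervals and signal criteria, demographic and outcome summaries, and
    time-to-onset analysis. Includes a synthetic FAERS generator with
    planted drug-event signals and known ground truth so every stage is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
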