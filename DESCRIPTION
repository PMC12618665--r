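Package: woar
Title: Weight of Advice and Appropriate Reliance Analysis for Human-AI Reader Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing multi-stage reader studies in which clinicians
    estimate a continuous quantity (here gestational age from fetal ultrasound),
    first unaided and then with access to the predictions and explanations of a
    machine-learning model. Implements the Weight of Advice reliance metric with
    its near-agreement exclusion rule, a behaviour-based classifier of
    appropriate, under- and over-reliance for regression advice, agreement with
    binned model predictions, per-participant performance and confidence
    summaries, and the battery of statistical comparisons used in such studies
    (t-tests with Cohen's d, exact small-sample Wilcoxon signed-rank and
    Mann-Whitney U tests, correlation, paired log-ratio tests). Because reader
    study data are rarely shareable, the package ships a calibrated behavioural
    simulator that generates three-stage study tables with realistic population
    structure, so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    readr,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
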