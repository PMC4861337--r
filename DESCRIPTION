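Package: chnri
Title: Scoring, Agreement and Rank-Stability Analysis for CHNRI
    Research Priority-Setting Surveys
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing expert-panel surveys conducted with the
    Child Health and Nutrition Research Initiative (CHNRI) methodology for
    setting health research priorities.  Encodes categorical expert
    responses (Yes / No / Undecided / Insufficiently informed), computes
    per-criterion percentage scores, the optionally weighted Research
    Priority Score (RPS), the Average Expert Agreement (AEA) statistic and
    ranked priority lists; quantifies robustness of the ranking to the
    expert panel by bootstrap resampling and reports the AEA-RPS
    association with permutation inference; and generates synthetic expert
    panels with controlled consensus, enthusiasm and missingness so that
    every pipeline stage can be validated without access to raw survey
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ggplot2,
    jsonlite,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
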