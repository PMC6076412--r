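Package: hccea
Title: Cost-Effectiveness Modelling of FOLFOX4 and Sorafenib in Advanced
    Hepatocellular Carcinoma
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A three-state (progression-free, progressed, dead) partitioned
    survival Markov cohort model comparing FOLFOX4 chemotherapy with sorafenib
    for advanced hepatocellular carcinoma in the Chinese setting. Provides a
    synthetic exponential survival-curve generator matched to published median
    overall and progression-free survival, body-surface-area based chemotherapy
    costing, a discounted monthly-cycle cohort engine with half-cycle
    allocation, incremental cost-effectiveness and net-benefit analysis under
    healthcare-system and patient-copayment perspectives, and one-way and
    probabilistic sensitivity analysis with cost-effectiveness acceptability
    curves. Results are returned as tibbles with broom-style tidiers and
    ggplot2 autoplot methods.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
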