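Package: cescore
Title: Severity and Need Scoring for Complex Emergencies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A config-driven scoring engine for comparing the severity of
    complex emergencies across countries and years. Four vulnerability and
    four exposure indicators are classified against per-indicator cut-offs
    into three ordinal severity levels (low/medium, high, extreme) carrying
    weights 0.5, 1.0 and 1.5; the two dimension sums are multiplied to give
    a severity score on a 4-36 scale, and multiplying by millions of people
    in need gives a need score. Includes heat-map and bar-chart reporting
    with the standard yellow/orange/red colour semantics, a rank-concordance
    reliability check of severity scores against excess-mortality rates, a
    synthetic panel generator with known ground truth, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    jsonlite,
    optparse,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
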