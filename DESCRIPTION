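Package: striptrials
Title: Effect Sizes and Break-Even Economics for On-Farm Strip Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for paired on-farm strip trials (OFTs) of crop
    treatments: per-trial log response-ratio effect sizes, bootstrap
    normal-approximation confidence intervals for the overall mean effect,
    effectiveness fractions above response thresholds, linear and locally
    weighted (tricube) regression of yield response on baseline yield,
    crop-by-year fixed-effects models, and an empirical-CDF break-even
    analysis with three-scenario grain-price sensitivity. Includes a
    calibrated synthetic trial generator emulating a decade of Uruguayan
    grain OFTs (soybean, rice, maize, wheat, barley) so the full pipeline
    runs without access to raw per-site yields.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    boot,
    ggplot2
Config/testthat/edition: 3
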