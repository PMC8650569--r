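Package: mixbiofilm
Title: Growth Kinetics and Interaction Inference for a Four-Species Model Biofilm
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of a four-species model biofilm
    (Rhodocyclus sp., Pseudomonas fluorescens, Kocuria varians, Bacillus
    cereus) enumerated by plate counts. Implements a lag-logistic growth
    model with constrained least-squares estimation on log10 cfu,
    detection-limit censoring with randomized imputation and repeated
    two-way ANOVA / Tukey HSD testing, Mann-Whitney comparisons for
    species-omission designs, inference of a signed interspecies
    interaction network (amensalism, mitigation, facilitation, delay),
    community composition and steady-state analytics, and a synthetic
    colony-count generator emulating mono-culture, omission,
    full-community and planktonic designs with lognormal plate-count
    noise and a detection limit.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    deSolve,
    jsonlite,
    ggplot2
Config/testthat/edition: 3
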