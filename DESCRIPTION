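Package: campcea
Title: Cost-Effectiveness Modelling of Skin Substitutes for Diabetic Foot Ulcers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An eight-state weekly Markov cohort model for the cost-effectiveness
    of cellular, acellular and matrix-like skin-substitute products (CAMPs)
    used adjunctively with standard of care in chronic diabetic foot ulcers.
    Provides the published baseline transition probabilities, treatment-effect
    risk ratios and product-cost schedules as fixtures; random-effects
    (DerSimonian-Laird) meta-analysis of two-arm event tables; incremental
    cost-effectiveness ranking with simple and extended dominance; one-way and
    horizon scenario sensitivity analysis; and probabilistic sensitivity
    analysis with cost-effectiveness acceptability curves. Synthetic-data
    generators reproduce the uncertainty structure of every input so the full
    pipeline can be exercised without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    metafor,
    withr,
    ggplot2
Config/testthat/edition: 3
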