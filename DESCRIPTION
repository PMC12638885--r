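Package: metstab
Title: Multi-Model Stability Analysis for Multi-Environment Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for analysing balanced multi-environment trials (METs) in
    plant breeding. Implements yield relative to the environmental maximum
    (YREM), joint ANOVA with the AMMI decomposition of the genotype-by-
    environment interaction, REML variance components and BLUPs for the
    balanced randomized-complete-block MET, genetic-parameter summaries
    (heritability, selection accuracy, genotype-environment correlation),
    the WAASB and WAASBY stability indices, and multi-trait genotype
    selection via the MTSI ideotype-distance index with selection
    differential and expected genetic gain. Includes a seeded synthetic MET
    generator with known ground truth and an end-to-end pipeline that writes
    all stage tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    readr,
    rlang,
    jsonlite
Suggests:
    lme4,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
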