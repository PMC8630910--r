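Package: monoqtl
Title: Single-Cell qPCR eQTL Mapping with Dropout-Aware Mixed Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for expression quantitative trait locus (eQTL) analysis of
    single-cell qPCR panels in purified immune cell subsets, such as classical
    and non-classical monocytes. Provides quality control and threshold-cycle
    (CT) transformation for Fluidigm-style CT matrices, an ensemble of four
    dropout-aware association methods with person-level random effects
    (Tweedie, logistic, Gaussian-on-detected and on-proportion ANOVA),
    Benjamini-Hochberg retention, cross-cell-type eQTL sharing bookkeeping,
    person-level on/off expression-pattern detection, individual-averaged
    correlation PCA for co-expression modules, and a seeded synthetic-data
    generator with known ground truth for calibration and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    glmmTMB,
    jsonlite,
    lme4,
    lmerTest,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
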