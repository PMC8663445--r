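Package: syncopedx
Title: Likelihood-Ratio Differential Diagnosis and Risk Stratification for Syncope
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Clinical decision support engine for transient loss of
    consciousness. Computes a ranked differential diagnosis over four
    etiologies (vasovagal, orthostatic, cardiogenic, neurogenic loss of
    consciousness) by accumulating published likelihood ratios on the
    log-odds scale, applies clinical-override weighting for etiologies
    with sparse literature, stratifies risk with the Canadian Syncope
    Score, and assembles disposition and testing recommendations. Ships a
    declarative JSON knowledge base, a synthetic-case generator that
    inverts likelihood ratios to sensitivity/specificity, an append-only
    evaluation log with an app-vs-user congruence report, and a command
    line interface.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
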