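Package: csflink
Title: Peripheral Blood to Cerebrospinal Fluid Biomarker Association in
    Prodromal Alzheimer's Disease
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Links peripheral blood readouts to cerebrospinal fluid (CSF)
    biomarkers in late mild cognitive impairment (LMCI) cohorts. Estimates
    relative immune-cell abundances from bulk blood expression with a
    single-sample gene-set enrichment score (weighted Kolmogorov-Smirnov
    running sum), screens peripheral markers against CSF amyloid-beta, TAU
    and PTAU by Pearson correlation, fits canonical correlation analysis
    with the full sequential Wilks/Rao inference, loadings, cross-loadings
    and redundancy indices, and evaluates single and logistic-combined
    markers by ROC analysis. A synthetic cohort generator with planted
    ground truth (latent cell abundances, a shared CSF-peripheral canonical
    factor, and group mean shifts) closes the testing loop without
    restricted clinical data.
License: MIT
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
    rlang,
    stats,
    tibble,
    utils
Suggests:
    fgsea,
    knitr,
    pROC,
    rmarkdown,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
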