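Package: nciigen
Title: Combining Ability, Heterosis and Variance Components for North
    Carolina Design II Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative-genetic analysis of North Carolina Design II
    (factorial) mating designs evaluated over replicates and years, as used
    for leaf mineral content in Gynandropsis gynandra. Provides restricted
    maximum likelihood (REML) variance-component estimation with best linear
    unbiased prediction (BLUP) for four mixed models (per-year and
    across-year genotype models, and per-year and across-year general/
    specific combining ability models with heterogeneous per-year residual
    variances), likelihood-ratio tests for variance components, derived
    quantitative-genetics statistics (additive and dominance variance,
    broad- and narrow-sense heritability, degree of dominance, Baker's
    predictability ratio, genetic advance), mid- and best-parent heterosis,
    Spearman association panels, and a synthetic Design II phenotype
    generator with known genetic architecture for validation.
License: MIT + file LICENSE
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
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    knitr,
    lme4,
    optparse,
    readxl,
    rmarkdown,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
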