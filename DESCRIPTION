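Package: nbmm
Title: Negative Binomial Mixed Models for Correlated Microbiome Count Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Fits negative binomial mixed models (NBMMs) for detecting
    associations between host environmental/clinical factors and microbiome
    count features when samples are hierarchically structured (families,
    litters, repeated measures). Sequencing depth enters as a log offset,
    over-dispersion is governed by the negative binomial shape parameter,
    and within-group correlation is captured by a random intercept. Models
    are fitted by an iterative weighted least squares (IWLS / penalized
    quasi-likelihood) algorithm that alternates pseudo-data construction,
    weighted linear mixed model updates via profiled REML, and
    Newton-Raphson updates of the shape parameter. Includes the standard
    comparator analyses (negative binomial regression without random
    effects, linear mixed models on log or arcsine square root transformed
    relative abundances, and a plain linear model), a simulation framework
    for type-I error and power studies on clustered count data, and a
    per-feature screening pipeline for count tables with sample metadata.
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
    MASS,
    nlme,
    lme4,
    optparse,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
VignetteBuilder: knitr
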