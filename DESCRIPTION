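Package: metaboclock
Title: Demography-Linked Metabolomic Aging Clocks for Genetically
    Replicated Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for linking cohort demography to age-structured
    metabolomic profiles in genetically replicated populations such as
    inbred Drosophila panels. Fits the Gompertz-Makeham mortality model
    to interval-censored death records by maximum likelihood, computes
    Kaplan-Meier restricted mean lifespans and log-rank comparisons,
    screens age-specific functional phenotypes (fecundity, climbing
    activity) against demographic parameters, fits per-metabolite
    age-by-genotype linear models with Benjamini-Hochberg false
    discovery control, and builds an elastic-net metabolome clock whose
    residual (age acceleration) is tested against lifespan, baseline
    mortality, and rate of aging. A synthetic-data generator reproduces
    the statistical structure of such studies so that the whole
    pipeline is testable without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    survival,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    glmnet
Config/testthat/edition: 3
NeedsCompilation: yes
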