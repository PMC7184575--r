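Package: mkblup
Title: Multi-Kernel BLUP Prediction of Grain Yield from Genomic and
    Physiological Data in Multi-Environment Trials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for multi-environment genomic and phenomic prediction of
    grain yield in inbred small-grain panels. Builds genomic (G = XX'/n) and
    physiological-trait (P = SS'/m) relationship kernels together with their
    reaction-norm genotype-by-environment and physiology-by-environment
    interaction kernels, and fits six multi-kernel BLUP models by Gibbs
    sampling. Includes marker quality control and imputation, derived
    physiological traits (membrane thermostability, thermal time, senescence
    rate, stay-green), mixed-model least-squares means and broad-sense
    heritability, population-structure-stratified cross-validation with
    heritability-adjusted accuracy, response-to-selection evaluation,
    elastic-net trait-importance ranking, and a synthetic-data generator
    emulating an un-replicated augmented trial design with repeated checks.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    lme4,
    vcfR,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    glmnet,
    mclust,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
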