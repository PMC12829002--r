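Package: spatialgblup
Title: Spatial GBLUP Genomic Evaluation for Smallholder Dairy Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Genomic evaluation of test-day milk yield in smallholder dairy
    populations where herds are tiny (mostly a single cow) and environmental
    variation is strongly spatial. Fits GBLUP mixed models with independent
    herd effects and/or a Matern-covariance spatial effect over herd GPS
    locations by Markov chain Monte Carlo, and compares models with WAIC,
    realised spatial variance, contribution correlations, and cross/forward
    validation of phenotype prediction. Includes a synthetic-data generator
    that emulates the admixed smallholder data structure with known ground
    truth, a VanRaden genomic relationship matrix with genotype quality
    control, and a deterministic mixed-model-equations solver used both for
    fast validation refits and as an oracle for the sampler.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
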