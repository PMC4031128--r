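Package: clrda
Title: Compositional Feature Selection for Case-Control Microbiome Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Identifies taxa associated with a binary phenotype in 16S
    rRNA count tables while respecting their compositional nature. Couples
    the centered log-ratio transform of operational taxonomic unit (OTU)
    relative abundances with sparse Partial Least Squares Discriminant
    Analysis, tunes sparsity and component count by stratified
    cross-validation, and assesses per-OTU significance with bootstrap
    coefficient distributions referenced against a permutation null.
    Ships alpha-diversity metrics with rarefaction, Bray-Curtis distances
    with ANOSIM, binomial prevalence estimates, a synthetic two-class
    cohort generator with known ground truth, and a command-line
    interface over QIIME classic tab-delimited OTU tables and mapping
    files.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    tools,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
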