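Package: lgcblup
Title: Multi-Population Genomic Prediction with Local Genetic
    Correlation GBLUP Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Genomic prediction for a trait measured in two populations,
    treating the population-specific performances as two correlated traits.
    Implements VanRaden genomic relationship matrices, recursive LD-block
    partitioning of the genome, bivariate multi-kernel average-information
    REML with heritability and genetic-correlation estimation, per-block
    local genetic correlation (LGC) estimation with likelihood-ratio
    p-values, region classification into SIG/NON or POS/NEG/RES SNP sets,
    GBLUP solvers for single-trait, combined, multi-trait and
    partitioned-kernel (LGC) models, repeated stratified cross-validation
    with accuracy and unbiasedness metrics, and a two-population simulator
    with controlled local genetic correlations. Reads and writes PLINK 1.9
    binary genotypes, GCTA binary GRMs and plain TSV interchange formats.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
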