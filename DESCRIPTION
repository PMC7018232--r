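Package: factorqtl
Title: Sparse Tensor Decomposition of Multi-Condition Expression and
    Component-Based Trans-eQTL Mapping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Decomposes a three-way gene-expression tensor (individuals by
    genes by conditions) into latent components with a spike-and-slab
    sparsity prior fitted by mean-field variational inference, calls sparse
    components with a sparsity ranking statistic, maps component individual
    scores to genotype dosages as trans-eQTLs with Benjamini-Hochberg FDR
    and a permutation empirical null, performs cis-eQTL mapping with
    latent-factor correction, and quantifies mediation of trans effects
    through cis genes by single-instrument Mendelian randomization. Ships a
    synthetic-data generator with planted ground truth so the whole pipeline
    is testable without any cohort download.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tools,
    utils,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
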