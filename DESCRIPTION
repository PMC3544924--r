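Package: cgsa
Title: Candidate Gene Set Association Testing with Variance-Component Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Gene-set level association testing for quantitative traits using
    mixed linear models. SNPs belonging to a functionally defined gene set
    (for example a signalling pathway) are summarised into additive and
    dominance relationship matrices via PLINK-style method-of-moments
    identity-by-descent estimation, epistatic kernels are formed as Hadamard
    products, and set-level additive, dominance and epistatic variance is
    estimated by restricted maximum likelihood and tested with boundary
    chi-square mixture likelihood-ratio tests. Includes a Hardy-Weinberg
    genotype simulator, replicate-based power and type-I-error studies
    comparing the gene-set test against a single-SNP candidate-gene baseline,
    and interval co-localization of candidate genes with QTL confidence
    intervals.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    ggplot2,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
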