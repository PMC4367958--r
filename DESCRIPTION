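Package: haplopred
Title: Genomic Prediction with LD-Based Haplotype Blocks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds haplotype blocks (haploblocks) from phased SNP panels by
    requiring a minimum pairwise D-prime between every two markers in a block,
    encodes blocks and single SNPs as dosage design matrices, and fits weighted
    BLUP and four-component Bayesian mixture models for genomic prediction of
    de-regressed proofs with a pedigree polygenic effect, by Gibbs sampling.
    Includes a forward simulator (founder haplotypes with tunable adjacent-locus
    linkage disequilibrium, gene dropping through a multi-generation pedigree,
    sparse-mixture QTL architectures, de-regressed proofs with heterogeneous
    reliabilities), phased-VCF input/output with marker quality control,
    pedigree relationship matrices, and evaluation tools: prediction
    reliability, bias regression, Hotelling-Williams tests for dependent
    correlations, and top-k selection overlap across a scenario grid.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    vcfR,
    withr,
    jsonlite
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
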