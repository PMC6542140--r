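Package: fireantdemog
Title: Demographic Inference for Invasive Fire Ants from RAD-Seq SNPs and
    Sequence Triplets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Coalescent demographic inference for the two invasive fire ant
    species Solenopsis invicta and S. richteri. Implements RAD-seq SNP
    filtering (depth, per-population call rate, minor allele frequency,
    physical spacing, sample missingness), DIYABC-style summary statistics
    (gene diversity, Weir-Cockerham F_ST), rejection approximate Bayesian
    computation with weighted local-linear regression adjustment and a PCA
    goodness-of-fit check for a four-population founder-bottleneck scenario,
    a full maximum-likelihood isolation versus isolation-with-migration test
    on three-sequence alignments under the multispecies coalescent with
    Gauss-Legendre quadrature and JC69, and conversion of scaled estimates
    (theta, tau) into effective sizes, divergence times in generations and
    years, and founding-queen counts for haplodiploid species.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    pracma,
    stats,
    utils,
    vcfR,
    Biostrings,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
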