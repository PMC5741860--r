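Package: hbdpart
Title: Age-Based Partitioning of Genomic Inbreeding with Multiple
    HBD-Class Hidden Markov Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Models individual genomes as mosaics of homozygous-by-descent
    (HBD) and non-HBD segments whose lengths are exponentially distributed
    with class-specific rates, so that autozygosity can be partitioned into
    age-related classes (longer segments trace to more recent common
    ancestors).  Provides the mixture hidden Markov model (1R, KR and MixKR
    parameterizations), forward-backward and Viterbi decoding, constrained
    expectation-maximization fitting and BIC model selection; genome-wide
    and threshold-based inbreeding coefficients; the classical marker-based
    estimators (homozygosity, excess homozygosity, two genomic-relationship
    variants, uniting-gametes correlation) and exact pedigree inbreeding;
    a rule-based sliding-window runs-of-homozygosity caller with per-panel
    presets; PLINK text and VCF input (including genotype likelihoods) with
    standard quality-control filters; and a mosaic-genome simulator with
    gene dropping that supplies ground truth for every estimator.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    Rcpp,
    vcfR
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
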