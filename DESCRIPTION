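Package: ktheta
Title: Evolutionary-Genetic Species Delimitation with the K/theta (4x) Rule
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Delimits evolutionary-genetic species in asexual and clonal
    organisms from single-locus alignments using the K/theta ("4x") rule:
    two well-supported sister clades are called distinct species when the
    corrected mean between-clade divergence K exceeds about four times
    theta = 2*Ne*mu, estimated from within-clade nucleotide diversity.
    Includes uncorrected and multiple-hit-corrected pairwise distances,
    neighbor-joining tree building with bootstrap support, the recursive
    delimitation procedure with sample-size-adjusted multipliers, and a
    Kingman-coalescent Monte-Carlo engine that validates the criterion's
    probability claims (TMRCA bounds, conditional reciprocal-monophyly
    probabilities) and generates synthetic aligned sequences for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    phangorn,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
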