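Package: polygc
Title: Genomic Control for Non-Additive Association Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Genomic-control correction of genome-wide association scans run
    under non-additive genetic models.  For recessive, dominant and
    over-dominant single-degree-of-freedom tests the inflation of the test
    statistic under population substructure depends on allele frequency; the
    package provides the analytic variance inflation factor (VIF) as a
    function of coded-allele frequency, inbreeding F and a case-control
    design coefficient K, estimation of (F, K) from a genome scan (VIFGC),
    a polynomial genomic control (PGC) that models the correction factor as
    a cubic in allele frequency (applicable also to the two-degree-of-freedom
    genotypic test), and a robust 2df test built from corrected recessive and
    dominant statistics.  Includes score tests for five inheritance models on
    binary and quantitative traits, a stratified-population simulator with
    liability-threshold phenotypes, and a type-1-error / power evaluation
    harness stratified by allele frequency.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
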