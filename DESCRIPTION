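Package: mbgpsim
Title: Multi-Breed Genomic Prediction with Simulated Cattle Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward-in-time simulation of beef-cattle populations with
    distinct linkage-disequilibrium histories, and genomic evaluation of
    mixed multi-breed reference populations. Simulates a multi-chromosome
    genome with biallelic markers and QTL, historical drift phases, and
    recent EBV-based selection; applies marker quality control; builds
    pedigree (A), genomic (G, weighted G) and single-step (H) relationship
    matrices; solves the mixed-model equations by preconditioned conjugate
    gradients for PBLUP, GBLUP, ssGBLUP and window-weighted wGBLUP; and
    screens donor animals by multidimensional scaling of identity-by-state
    distances to assemble mixed reference populations at chosen ratios.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    Rcpp,
    stats,
    utils,
    methods
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
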