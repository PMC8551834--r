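Package: hapstep
Title: Haplotype-Based Single-Step Genomic Prediction in Simulated
    Livestock Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Forward-in-time simulation of purebred and composite livestock
    breeding programs (historical bottleneck, phenotypic and BLUP-EBV based
    selection, admixed composites), linkage-disequilibrium characterisation
    (r2, LD- and inbreeding-based effective population size), LD-threshold
    haplotype blocking with pseudo-SNP dosage encoding, and single-step
    genomic BLUP (ssGBLUP) evaluation with VanRaden genomic relationship
    matrices, blended H inverse, REML variance components and a
    preconditioned conjugate-gradient mixed-model solver. Includes the
    scenario machinery to compare individual-SNP and haplotype-based
    predictions (accuracy and dispersion bias of GEBVs) across populations
    of differing genetic diversity.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    Rcpp,
    vcfR
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
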