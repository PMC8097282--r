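Package: aiscan
Title: Detecting Adaptive Introgression and Estimating Selection from Local Ancestry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Hidden Markov model scan for adaptively introgressed loci in
    admixed population samples. Models the distortion of ancestry
    tract-length distributions around a positively selected introgressed
    allele under a one-pulse admixture model, computes position-dependent
    ancestry-transition rates (by forward iteration of a two-locus
    hitchhiking recursion or by a four-point parametric approximation),
    and estimates per-site selection coefficients by maximizing a
    windowed likelihood ratio with golden-section search. Supports read
    pileup, called genotype and pooled observations at arbitrary ploidy.
    Includes a Wright-Fisher forward simulator with exact ancestry tract
    recording (additive, dominant, recessive and two-locus incompatibility
    selection), reference-panel synthesis and short-read simulation for
    end-to-end validation, plus neutral-simulation calibration of
    likelihood-ratio thresholds.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    optparse
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
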