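Package: kernelscreen
Title: Virtual Time-Domain NMR Pipeline for Oil-Content Screening of Seeds
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates and analyses single-kernel time-domain NMR
    measurements for oil-content based seed screening, as used to sort
    haploid from diploid maize kernels in doubled-haploid breeding.
    Provides a bi-exponential spin-echo signal model for the oil and
    bound-water proton pools, echo-train decomposition by single-echo
    isolation or full nonlinear least-squares fitting, linear
    signal-to-mass calibration, oil-content-ratio (OCR) computation,
    Gaussian two-class threshold classification with analytic and
    empirical error rates, and a synthetic population generator so the
    whole pipeline runs without instrument hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    mclust,
    minpack.lm,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
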