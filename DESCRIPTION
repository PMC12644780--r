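Package: tissuedrt
Title: Distribution of Relaxation Times Analysis for Tissue Impedance Spectroscopy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Inverts electrical impedance spectra of biological tissue into a
    distribution of relaxation times (DRT) by nonnegative Tikhonov-regularized
    least squares, separates electrode polarization from the tissue response by
    relaxation-time thresholding, decomposes the tissue DRT into Gaussian
    components in log relaxation time with F-test model selection, and
    quantifies each compartment's contribution to the DC resistance. Includes
    a forward simulator of two-electrode tissue spectra (Debye, Cole-Cole,
    log-normal and finite-length Warburg dispersion elements), tools for
    monitoring reversible and irreversible electroporation from paired
    pre/post spectra, and order-of-magnitude thermal calculations for pulse
    protocols.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    minpack.lm,
    pracma,
    stats,
    utils
Suggests:
    withr,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
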