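Package: dpoaewave
Title: Wave-Interference Modelling of Distortion-Product Otoacoustic Emissions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Models the generation of 2f1-f2 distortion-product otoacoustic
    emissions (DPOAEs) in the mouse cochlea as wave interference between
    distortion sources distributed along the basilar membrane (BM). A
    parametric generator produces mouse-like single-tone BM frequency
    responses (compressive gain, level-dependent tuning, traveling-wave
    phase accumulation); scaling symmetry and a frequency-to-place map turn
    them into spatial traveling-wave profiles; a first-order Boltzmann
    mechanotransduction nonlinearity with membrane low-pass filtering
    generates distortion products at each cochlear location; and vector
    summation of the distortion products reaching the stapes yields DPOAE
    ratio functions. Includes tuning-sharpness metrics (Q10dB, equivalent
    rectangular bandwidth), spectral measurement conventions, and a
    config-driven pipeline that reproduces the model's bandpass ratio
    functions and their level-dependent tuning.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    yaml,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
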