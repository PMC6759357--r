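Package: zwuisdp
Title: Zwuis Stimulus Design and Distortion-Product Analysis of Outer Hair Cell Motility
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for in vivo system identification of the outer-hair-cell
    (OHC) motile pathway from cochlear vibration recordings. Designs zwuis
    multitone stimuli whose intermodulation products up to third order are
    uniquely attributable to their parent primaries, simulates a synthetic
    cochlea (input shaping, rectifying nonlinearity, first-order low-pass
    motile path, linear path, displacement noise), performs coherent Fourier
    analysis with Rayleigh phase-stability testing, catalogues and corrects
    second-order distortion products (DP2s), retrieves the effective OHC
    input by bilinear log-domain inversion, drives an iterative stimulus
    equalization loop, and estimates the OHC corner frequency by jointly
    fitting a first-order low-pass filter to DP2 magnitudes and phases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    withr
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
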