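Package: dinoise
Title: Modelling Digit-in-Noise Perception Through a Degradable Auditory Periphery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An end-to-end simulation of digit-in-noise speech perception. Synthetic
    spoken-digit tokens are calibrated in dB SPL, mixed with white noise, and passed
    through a phenomenological auditory periphery with configurable audiometric
    (outer/inner hair cell), medial olivocochlear reflex (MOCR), and auditory-nerve-fiber
    degradations to produce population neurograms. A small convolutional network is
    trained to identify the digit from the neurogram under three adaptation paradigms
    (normal-hearing control, unconstrained, and last-layer-constrained), and the
    resulting accuracy-versus-SNR tables are reduced to psychometric sigmoid fits,
    50%-correct SNR thresholds, confusion analyses, and repeated-measures factorial
    statistics. Reference-based neurogram similarity metrics (NSIM, STMI) are included.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    graphics,
    grDevices,
    signal,
    minpack.lm,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
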