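Package: combetSNR
Title: Signal-to-Noise Ratio Measurement for Magnetic Resonance Images
    from Noise-Image and Subtraction Methods
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Measures the signal-to-noise ratio (SNR) of magnitude
    magnetic-resonance images from a signal image plus a fully attenuated
    noise image acquired with the maximum diffusion weighting and the
    longest echo time, with central-chi corrections for multichannel
    sum-of-squares reconstruction. Also provides the long-echo-only
    (double-echo) and image-subtraction reference estimators, circular and
    mask regions of interest, 7x7 sliding-window signal/noise/SNR maps,
    repeatability (coefficient-of-variation) and slice-thickness linearity
    analyses, and a multichannel phantom acquisition simulator with a
    spin-echo/diffusion signal model so every estimator can be validated
    against known ground truth. Images are exchanged as NIfTI-1 files with
    JSON sidecar metadata; a command-line entry point ties the simulator
    and estimators into a reproducible quality-assurance workflow.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    RNifti,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
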