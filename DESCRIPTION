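Package: comboct
Title: Frequency-Comb and Broadband Source Simulation for Spectral-Domain
    Optical Coherence Tomography
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis toolkit for spectral-domain optical
    coherence tomography (SD-OCT) with discrete frequency-comb illumination,
    such as dissipative Kerr soliton (DKS) microcombs, alongside conventional
    superluminescent-diode (SLD) sources. Provides parametric source models
    (sech-squared soliton combs, chaotic modulation-instability combs,
    Gaussian SLD spectra), relative-intensity-noise (RIN) estimation with
    shot-noise and excess-photon-noise floors, multichannel intensity-noise
    simulation with separable common-mode and per-line components, a
    spectrometer-pixel interferogram forward model with ambiguity-range
    folding, two tomogram reconstruction pipelines (full-interferogram and
    comb-tone subsampled), cross-correlation and cross-spectral analysis of
    per-line detector traces, and synthetic phantom/scenario generators with
    recorded ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    Matrix,
    utils,
    tools,
    grDevices,
    graphics,
    signal,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
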