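Package: vignetta
Title: Stimulus Vignetting: V1 Energy-Model Simulations and Phase-Encoded
    fMRI Analysis
Version: 0.1.0
Authors@R:
    person("Vignetta", "Developers", email = "vignetta@example.org",
           role = c("aut", "cre"))
Description: Tools for studying stimulus vignetting, the spread of Fourier
    energy produced by any aperture or contrast modulation bounding a
    grating, which induces coarse-scale orientation biases in population
    responses that are not due to neural orientation tuning. Provides a
    frequency-domain steerable-pyramid energy model of primary visual
    cortex (V1), generators for vignetted grating stimuli (oriented
    carriers multiplied by radial or angular polar modulators inside a
    raised-cosine annulus), population-receptive-field (pRF) sampling of
    model output, a synthetic phase-encoded fMRI session generator, the
    corresponding cosine/coherence voxelwise analysis, and a multivariate
    pattern analysis suite (leave-one-run-out decoding with label
    shifting, Fourier phase-randomization permutation tests, and
    representational similarity analysis with multidimensional scaling).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    data.table
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
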