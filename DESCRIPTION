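Package: arfoce
Title: Lamb-Wave Optical Coherence Elastography Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for acoustic-radiation-force optical coherence
    elastography (ARF-OCE) of thin, fluid-immersed tissue plates such as the
    optic nerve head. Converts phase-sensitive M-B-mode OCT data cubes to
    axial displacement by phase-resolved Doppler processing, estimates
    phase-velocity dispersion by two-dimensional Fourier (k-space) analysis,
    maps local wave speed across the imaging region, and inverts the
    zero-order antisymmetric (A0) Lamb-wave model for Young's modulus. A
    synthetic-data module generates dispersive A0 wavefields with known
    mechanics and realistic interferometric phase noise so that every stage
    of the pipeline is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    grDevices,
    jsonlite,
    png,
    rhdf5,
    signal,
    stats,
    tiff,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
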