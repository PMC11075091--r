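Package: eictsim
Title: Edge-Illumination X-Ray Phase-Contrast Micro-CT Simulation and
    Reconstruction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulator and reconstruction toolkit for edge-illumination (EI)
    x-ray phase-contrast micro-CT with aperture-driven, adjustable in-slice
    resolution. Models the optical chain (source, multi-band sample mask,
    detector mask, detector), simulates illumination curves and
    beamlet-sampled projections of synthetic refractive-index phantoms,
    schedules dithered and cycloidal (fly-scan) acquisitions, assembles
    sinograms with flat/dark correction, jitter reversal and spline
    regridding, performs single-image phase retrieval and filtered back
    projection, quantifies bar-pattern modulation versus mask-aperture
    width, and provides a Noise2Inverse-style self-supervised denoising
    harness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
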