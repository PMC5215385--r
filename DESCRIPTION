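Package: holotrace
Title: Scanless Holographic Two-Photon Imaging: Hologram Synthesis and
    High-Speed Calcium Trace Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Computational toolbox for scanless two-photon imaging with
    holographic multi-spot illumination. Synthesizes spatial light
    modulator phase masks with a weighted Gerchberg-Saxton iterative
    Fourier-transform algorithm including per-site intensity
    compensation, and provides a high-speed calcium imaging analysis
    pipeline: ROI trace extraction with ring background, dF/F0 and dF/bg
    normalization, threshold-based calcium event detection with
    four-parameter transient fitting, signal-to-noise and spike-matching
    statistics, pairwise and network correlation measures, optical
    crosstalk metrics, and a Monte Carlo shell-model simulation of
    neuropil and neighbor-cell contamination. A synthetic-data generator
    emulates GCaMP6-like fluorescence driven by sparse or bursting spike
    trains so that every analysis stage is testable without microscope
    or electrophysiology hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    jsonlite,
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    tiff,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
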