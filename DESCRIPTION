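Package: cinegate
Title: Cine-MRI Motion Analysis for Gating Selection in MR-Guided Lung SBRT
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying gross target volume (GTV) motion on
    sagittal cine-MRI acquired on an MR-Linac and for supporting the choice
    between free-breathing (FB) and deep-inspiration breath-hold (DIBH)
    gated delivery of lung stereotactic body radiotherapy. The package
    segments the coloured tracking overlays burned into exported cine
    frames (red GTV contour, yellow gating boundary), computes per-frame
    centroid positions in patient coordinates, summarises motion as the
    standard deviation of the centroid per axis, detects breath-hold
    plateaus in DIBH traces, simulates the 5% outside-boundary gating rule,
    and applies a 2 mm motion criterion for FB eligibility with 3 mm versus
    5 mm planning margins. A ground-truthed synthetic cine generator
    (respiratory waveform, rendered overlay frames, PNG stacks) makes the
    whole pipeline testable without patient data, and bundled cohort tables
    support the correlation screen and DVH-difference aggregation of the
    accompanying decision workflow.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    mgcv,
    png,
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
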