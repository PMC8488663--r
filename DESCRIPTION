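Package: chronodelay
Title: Circadian Phase, Sleep and Memory Analysis for Dim-Evening-Light Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis chain for mouse studies of dim light in the evening (DLE):
    moving-average phase-marker extraction (activity onset, midpoint, offset)
    from passive-infrared locomotor recordings, immobility-defined sleep
    scoring, 2^-ddCt quantitative PCR rhythm normalization with
    center-of-gravity acrophase and phase-shift estimation, wavelet-based
    analysis of shutter-gated in vivo bioluminescence rhythms (background
    correction, circadian-band detrending, acrophase, period, signal-to-noise
    ratio), and a sliding-window sleep-history scan of recognition-memory
    performance with mixed-effects inference (likelihood-ratio test and
    parametric-bootstrap confidence intervals). Includes a synthetic-data
    generator that emulates every input modality with known ground truth so
    the full pipeline is testable by parameter recovery.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    lme4,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
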