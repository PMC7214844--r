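Package: veinpulse
Title: Flow Pulsatility in Small Cerebral Veins from Cardiac-Gated
    Phase-Contrast MRI
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for cardiac-gated 2D phase-contrast MRI of
    small cerebral cortical veins: vessel segmentation by magnitude
    thresholding and 8-connected clustering, background-phase removal by
    2D median filtering, temporal phase unwrapping, per-cluster velocity
    waveform extraction with venc scaling, a dedicated superior sagittal
    sinus reference pathway, the pulsatility contrast-to-noise ratio
    (PCNR) statistic with Monte Carlo null calibration, pulsatility index,
    temporal lag by circular cross-correlation, and cohort-level group
    statistics. Includes a synthetic phase-contrast scene generator with
    full ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    RNifti,
    Rcpp,
    signal,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
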