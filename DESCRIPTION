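Package: cingfp
Title: Cross-Species Cingulate Connectivity Fingerprints
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for data-driven analysis of cingulate cortex connectivity
    across species and modalities. Implements projection-similarity mapping of
    anterograde tracer experiment collections, spatial independent component
    parcellation of the resulting seed-by-voxel correlation maps, seed and
    target connectivity fingerprints from both tracer and resting-state fMRI
    data, scan-level functional-connectivity quality control, two-way fully
    within-subject repeated-measures ANOVA with Greenhouse-Geisser and
    Huynh-Feldt sphericity corrections, and quantitative comparison of
    connectivity fingerprints across species on a common rostro-caudal axis.
    Ships a synthetic phantom generator (atlases, tracer experiments, BOLD
    scans with planted network covariance) so the full pipeline can be
    exercised and validated end to end without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    signal,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
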