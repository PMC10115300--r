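Package: harborscape
Title: Soundscape Analysis for Duty-Cycled Estuarine Hydrophone Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for passive acoustic monitoring of urbanized estuaries:
    calibrated band-limited rms sound pressure level (SPL) extraction from
    duty-cycled hydrophone recordings, covariate assignment (lunar, tidal,
    diel, seasonal), annotation-based prevalence and chorusing summaries,
    anthropogenic-noise-exclusion re-analysis, and random-forest inference
    with shadow-feature importance ranking and Dunnett-Tukey-Kramer
    post-hoc comparisons. Includes a synthetic acoustic-scene generator
    (snapping shrimp, fish choruses, dolphin vocalizations, vessel noise)
    so the full pipeline can be exercised and validated without field data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    signal,
    randomForest,
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
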