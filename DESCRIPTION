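Package: leapmea
Title: Action Potential Morphology from Multiwell Microelectrode Array Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for cardiomyocyte recordings on multiwell
    microelectrode array (MEA) plates carrying both field-potential (FP) and
    high-amplitude local extracellular action potential (LEAP) signals.
    Provides zero-phase band filtering, electrode signal classification,
    beat detection and segmentation, amplitude-normalized beat averaging,
    action potential duration (APD30/50/90 and full APD curves), rise time,
    beat-period statistics, repolarization triangulation (APD50/APD90),
    automated early afterdepolarization (EAD) detection, field potential
    amplitude and duration with Fridericia rate correction, and well- and
    plate-level aggregation (stability time courses, dose-response
    summaries, pacing analysis, rank-sum group comparison). A synthetic
    plate simulator generates coupled AP/FP recordings with analytically
    known morphology so every stage can be validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
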