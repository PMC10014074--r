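Package: canineEP
Title: Cardiac Electrophysiology Biomarkers for a Two-Group Canine Exercise Cohort
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Beat-series electrocardiographic biomarkers and cellular
    electrophysiology feature extraction for a sedentary-versus-trained
    canine cohort design. Implements an individualized regression-based QT
    rate correction (QTc referenced to a fixed RR interval), beat-to-beat
    repolarization variability statistics (short-term variability and
    RMSSD), ventricular premature/escape beat classification and counting,
    action-potential APD90 and transient-outward current density
    extraction, Teichholz and cube-formula echocardiographic indices, and
    the normality-gated group-comparison layer.  A deterministic synthetic
    cohort generator provides ground-truthed beat streams, action-potential
    trains, voltage-clamp records, and echo panels so the whole pipeline is
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    graphics,
    utils,
    tools,
    nortest,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
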