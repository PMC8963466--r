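Package: imucheck
Title: Independent Monitor-Unit Second-Check QA for MR-Linac Adaptive Plans
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: File-based independent monitor-unit (IMU) second-check pipeline for
    high-field MR-Linac online adaptive plans. Transforms a Monaco-dialect DICOM
    RT Plan (143.5 cm SAD, collimator 0, MLC positions in tag MLCY, fixed 22 cm
    superior-inferior jaw) into a conventional-TPS dialect (100 cm SAD, MLCX,
    derived X jaws, extended-SSD technique), compares two independently computed
    per-beam 3D dose distributions on a beam's-eye-view parallel plane through
    the plan reference point, approximates the 1.5 T magnetic-field effect as a
    rigid lateral shift of the reference distribution, corrects the evaluated
    dose for posterior RF-coil attenuation, and scores agreement with 2D gamma
    analysis restricted to the complete irradiated area outline (CIAO). A
    deterministic toy divergent-beam dose engine generates matched and
    deliberately mismatched synthetic cases so the whole chain is testable
    offline, including a sensitivity study and pass/fail contingency analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports: stats, utils, graphics, grDevices, tools, yaml
Suggests: testthat (>= 3.0.0), withr, jsonlite
Config/testthat/edition: 3
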