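Package: thermocular
Title: Ocular Surface Temperature Extraction from Registered IR/VIS Eye Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Processing pipeline for dual-camera ocular surface temperature
    (OST) recordings: control-point based affine registration of synchronized
    infrared (radiometric) and visible-light eye-image sequences, mapping of
    cornea/sclera segmentation masks into the thermal frame, statistical
    removal of cold eyelash artifacts by a mean +/- 2 sigma outlier rule,
    blink-frame exclusion via the Eye Aspect Ratio, and per-frame region-of-
    interest temperature profiles. Includes registration-quality metrics
    (control-point RMSE and fiducial registration error) and a synthetic
    eye-phantom generator with full ground truth, so that every stage is
    testable without clinical recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    png,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
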