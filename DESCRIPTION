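Package: maScreen
Title: Microaneurysm Detection Scaffold for Retinal Fundus Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale scaffold for microaneurysm (MA) detection in colour
    retinal fundus photographs. Provides fundus image quality equalization
    (green-channel extraction, contrast-limited adaptive histogram
    equalization, Otsu foreground masking, quality screening), Pascal
    VOC-style patch dataset construction by sliding window, an
    attention-based multilayer feature-fusion neck with learnable layer
    weights and channel-wise softmax attention plus its composite training
    loss, secondary screening of candidate detections by spatial confidence
    against vessel segmentation masks with weighted voting, VOC2007
    detection metrics (IoU, greedy matching, 11-point average precision,
    F1), and a seeded synthetic fundus scene generator with ground-truth
    vessel masks, lesion masks and bounding boxes so every stage is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    igraph,
    jsonlite,
    png,
    stats,
    tools,
    utils,
    xml2,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
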