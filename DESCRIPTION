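Package: bactrack
Title: High-Throughput 2-D Video Tracking of Bacterial Motility
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects and tracks hundreds of swimming bacteria per frame in
    phase-contrast or brightfield video microscopy recordings. Detection uses
    grey-value thresholding (marker-gated dual adaptive thresholds, plain
    adaptive thresholding, or a rolling global threshold), tracking links
    detections across frames by least-distance assignment against the
    predictions of a constant-velocity finite-impulse-response filter, and a
    stringent multi-criterion selection ledger removes questionable tracks
    before per-track motility statistics (distance, speed, displacement,
    percent motile, turn points per second, arc-chord ratio) are computed.
    Includes a run-and-tumble trajectory simulator and a noisy video renderer
    so the whole pipeline can be validated against known ground truth, plus
    MJPEG/uncompressed AVI readers and writers, annotated overlay videos, and
    coordinate, rose and violin plots.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jpeg,
    stats,
    utils,
    grDevices,
    graphics,
    parallel,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
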