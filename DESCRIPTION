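Package: stripeqc
Title: Detection and Correction of Transcriptome-Wide Technical Anomalies
    in Time-Series Expression Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Quality control for time-series transcriptomic experiments.
    Detects STRIPEs (TRanscriptomic Irregular Profile Expression changes) --
    time points whose transcript-level distribution deviates
    transcriptome-wide from their temporal neighbors for technical reasons --
    using a sequential two-sample Kolmogorov-Smirnov procedure with
    forward/reverse anchoring, an all-by-all KS distance matrix, and a robust
    outlier-based threshold advisor. Corrects detected anomalies by monotone
    piecewise-cubic (PCHIP) interpolation, quantile normalization, or Z-score
    quantile normalization, and verifies corrections by re-detection at the
    same threshold. Quantifies downstream impact on periodicity analysis via
    a cosinor score, peak/trough anomaly-alignment over-representation,
    top-N ranking overlap, and subsampling sensitivity. Includes a periodic
    time-course simulator with injectable low/high/bimodal anomalies and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    pracma,
    stats,
    utils,
    grDevices,
    graphics,
    yaml
Suggests:
    limma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
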