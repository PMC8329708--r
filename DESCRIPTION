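Package: beeflight
Title: Spike Sorting and Flight-Behavior Correlation for Copter-Borne
    Honey Bee Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to extract single-unit activity from noisy two-channel
    extracellular recordings made from the brain of a honey bee carried by a
    quadcopter, and to relate that activity to flight behavior. Implements
    robust (median/MAD) signal normalization, gain-matched differential
    subtraction for common-mode motor-noise rejection, local renormalization,
    MAD-threshold and template-matching spike detection, Haar-wavelet/PCA
    feature extraction with Local Outlier Factor screening and hierarchical
    density-based clustering, 100-ms spike-rate binning, sliding repetition
    autocorrelation, lagged spike-rate/yaw-rate cross-correlation, and
    back-projection of spike rates through a compound-eye ray-casting model
    onto a terrain grid. A synthetic-data module generates trefoil flight
    telemetry, yaw-modulated inhomogeneous Poisson spike trains, and
    quantized two-channel recordings with realistic common-mode noise so the
    whole pipeline is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    mclust
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
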