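Package: rppgnet
Title: Efficient Spatiotemporal Attention Networks for Remote
    Photoplethysmography and Heart Rate Variability Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Recovers the remote photoplethysmography (rPPG) waveform from
    facial video with an efficient 3D spatiotemporal attention network built
    from depthwise-separable 3D convolutions, grouped shuffle attention
    (channel and spatial branches with channel shuffle), and a stacked
    convolutional GRU head, trained with a negative Pearson correlation loss.
    Includes the full downstream heart rate variability (HRV) pipeline:
    zero-phase FIR band-pass filtering, cubic-spline resampling to 256 Hz,
    peak detection, normal-to-normal interval extraction, time-domain
    (AVNN, SDNN, RMSSD) and frequency-domain (LFnu, HFnu, LF/HF) metrics, and
    agreement statistics. A closed-form complexity profiler reports per-layer
    multiply-accumulate and parameter counts, and a seeded synthetic-data
    generator produces facial-video/reference-PPG/ground-truth-interval
    triples for end-to-end validation without any external dataset.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    signal,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    png,
    yaml,
    optparse
Config/testthat/edition: 3
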