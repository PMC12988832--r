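Package: paviq
Title: Photoacoustic Ureter Visibility: Beamforming, ROI Metrics, and Dosimetry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies in vivo photoacoustic visibility of the ureter after
    methylene blue injection. Provides a synthetic linear-array channel-data
    generator for a tube-shaped absorber, delay-and-sum beamforming with
    envelope detection and log compression, segmentation-driven frame
    retention, an iterative constrained region-of-interest placement
    algorithm, contrast/SNR/generalized contrast-to-noise ratio (gCNR)
    quantification, nonparametric group comparison across post-injection
    time points (Kruskal-Wallis with Dunn's post hoc test), and laser
    fluence and dye dosimetry arithmetic.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    png,
    tiff,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
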