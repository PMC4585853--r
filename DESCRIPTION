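Package: ccrics
Title: Spatiotemporal Cross-Correlation Raster Image Correlation
    Spectroscopy
Version: 0.1.0
Authors@R:
    person("ccrics", "developers", email = "ccrics@example.org",
           role = c("aut", "cre"))
Description: Dual-color cross-correlation raster image correlation
    spectroscopy (ccRICS) for mapping molecular interaction and
    degradation in raster-scanned confocal time-lapse images.
    Implements moving-average detrending, FFT-based spatial auto- and
    cross-correlation with overlap normalization, nonlinear fitting of
    the RICS scanning/diffusion model along the fast-scan axis,
    relative cross-correlation amplitude (RCA) computation, ROI-tiled
    spatiotemporal RCA maps with intensity-modulated rendering, and
    exponential decay-kinetics fitting of RCA time courses.  A
    Brownian-dynamics raster-scan simulator of diffusing point
    emitters with Poisson shot noise provides ground-truth data for
    every stage.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
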