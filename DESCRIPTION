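Package: raftrack
Title: Segmentation, Tracking and Mobility Statistics for Fluorescent
    Membrane Microdomains
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for time-lapse fluorescence movies of
    punctate membrane microdomains (e.g. GFP-tagged receptor clusters in
    lipid rafts). Provides rolling-ball background subtraction,
    large-radius unsharp masking and threshold-based domain morphometrics;
    a-trous B3-spline wavelet spot detection with subpixel centroids;
    globally optimal frame-to-frame track linking under a physical speed
    cap without gap closing; per-track speed and confinement-ratio (rho)
    statistics with lifetime and stationarity screens; permutation tests
    for condition comparison; and a ground-truthed synthetic movie
    generator emulating diffusive versus clustered/immobilized receptor
    phenotypes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    EBImage,
    tiff,
    yaml,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
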