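Package: pulsecam
Title: Contactless Cardio-Respiratory Monitoring from RGB Video
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Continuous, contactless estimation of heart rate and respiratory
    rate from RGB video of a seated subject's face and torso. The respiratory
    waveform is recovered from chest-wall motion via Horn-Schunck optical flow
    over a torso region of interest; the cardiac pulse is recovered from
    remote photoplethysmography (r-PPG) at the cheeks and forehead through six
    post-processing techniques (green channel, MODWT multiresolution analysis,
    CHROM and POS chrominance projections, JADE ICA and PCA blind source
    separation). Per-second rate series are produced by sliding-window Lomb
    periodogram analysis with interquartile-range outlier replacement, and
    fused across regions by averaging or signal-to-noise-ratio selection.
    Includes a synthetic scene generator with known ground truth, apnea-based
    synchronization against reference recordings, and Bland-Altman agreement
    statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    signal,
    Matrix,
    EBImage,
    png,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
biocViews: Software, Visualization, BiomedicalInformatics
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'conditioning.R'
    'evaluation.R'
    'jade.R'
    'rate_estimation.R'
    'wavelet.R'
    'rppg_methods.R'
    'roi_detect.R'
    'video_io.R'
    'respiration.R'
    'synthgen.R'
    'pipeline.R'
    'pulsecam-package.R'
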