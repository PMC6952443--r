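Package: astroca
Title: Astrocyte Calcium Imaging and Hemodynamic Response Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: End-to-end analysis of two-photon astrocyte calcium imaging and
    concurrent hemodynamic recordings from experiments that lower cerebral
    perfusion pressure by raising intracranial pressure. Provides a synthetic
    two-channel movie and physiology generator with known ground truth,
    rigid plus combined local-global (CLG) optical-flow motion correction,
    time-varying baseline fluorescence estimation by truncated SVD with
    asymmetric iteratively reweighted least-squares smoothing, selective
    averaging transient detection (windowed PCA, clustering, 2-SD
    thresholding), adaptive-threshold ROI segmentation with compartment
    classification (somas, processes, perivascular endfeet), per-ROI event
    statistics (active time, frequency, duration, responder calls,
    peristimulus averages), and processing of intracranial pressure,
    arterial pressure and sympathetic nerve activity signals (cerebral
    perfusion pressure, MAP/heart-rate extraction, rectified-integrated
    nerve activity, stimulus-response delay).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    graphics,
    grDevices,
    Matrix,
    igraph,
    tiff,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
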