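Package: hvmflow
Title: Automated Quantification of Sublingual Microcirculation from Handheld Vital Microscopy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Fully unattended analysis of handheld vital microscopy (HVM) image
    sequences of the sublingual microcirculation. The pipeline stabilizes the
    sequence with sparse pyramidal Lucas-Kanade optical flow, detects vessel
    centerlines and diameters on the temporal mean image with a
    principal-curvature (Steger) line detector after contrast-limited adaptive
    histogram equalization, measures red blood cell velocity per capillary from
    automatically generated space-time diagrams (kymographs), and aggregates
    total vessel density (TVD), functional capillary density (FCD), proportion
    of perfused vessels (PPV) and length-weighted field red blood cell
    velocity. A synthetic scene generator with exact ground truth makes every
    stage testable without real recordings, and method-agreement utilities
    (Bland-Altman, ROC/AUC) support validation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    Rcpp,
    png,
    tiff,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    EBImage,
    pROC,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
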