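Package: gazemask
Title: Segmentation Masks from Eye-Tracking Gaze Traces
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Turns timestamped eye-tracking recordings of a reader visually
    tracing lesion borders into binary segmentation masks, and evaluates
    whether such gaze-derived (ET) masks can replace hand-annotated (HA)
    masks for training semantic-segmentation networks. Provides gaze-log
    parsing, dispersion-threshold fixation detection, time-windowed boundary
    trace extraction, convex-hull and polygon mask rasterization, a compact
    U-net training harness with negative-Dice loss, evaluation statistics
    (Dice coefficient, trimmed means, cluster-size-threshold ROC/AUC, TOST
    equivalence testing), and a synthetic lesion-phantom plus scanpath
    simulator so the full ET-versus-HA experiment runs end to end without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    png,
    EBImage,
    yaml,
    jsonlite,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    igraph,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
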