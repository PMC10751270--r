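Package: fexkit
Title: Facial Expression Analysis from Action Units to Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A desk-scale toolkit for facial expression analysis. Provides
    68-point landmark geometry, histogram-of-oriented-gradients (HOG) feature
    extraction within the landmark convex hull, PCA compression, per-action-unit
    and emotion classifiers with a training harness, a linear action-unit to
    landmark generative face model with stylized rendering and morph animation,
    a frames-by-features (Fex) data container with session-aware summaries,
    intersubject correlation, mass-univariate regression and cross-validated
    decoding, detection and robustness evaluation metrics (average precision,
    normalized landmark error, pose MAE, F1, luminance/occlusion/rotation
    perturbations), and a synthetic labeled-face generator so the whole
    pipeline can be trained and verified without external datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    e1071,
    xgboost,
    MASS,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    png
Config/testthat/edition: 3
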