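Package: kneewear
Title: Virtual Healthy Twin Reconstruction and Non-Linear Knee Cartilage
    Wear Pattern Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying cartilage wear patterns in end-stage knee
    osteoarthritis from bone surface geometry. Provides a synthetic cohort
    generator for articulated lower-limb meshes with controllable alignment
    (hip-knee-ankle angle, torsion, slope, bowing) and arthritic degradation
    (osteophyte-like outliers, joint-space narrowing, coronal misalignment);
    statistical shape modelling with robust iterative fitting and outlier
    exclusion to reconstruct a patient's pre-disease "virtual healthy twin";
    anatomically standardized joint-space-width maps flattened conformally to
    a square image domain; a principal polynomial autoencoder that decomposes
    non-linear wear patterns into ordered, decorrelated components with
    variance attribution; and downstream morphometric statistics (canonical
    correlation with permutation tests, Mahalanobis-normalized linear
    discriminant risk classification with leave-one-out cross-validation, and
    2-D shape-space embedding), together with end-to-end experiment harnesses.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    Matrix,
    mgcv,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
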