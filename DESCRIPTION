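Package: imagerisk
Title: Global Image-Feature Models for Cancer Risk and Prognosis Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and evaluating cancer risk and prognosis
    prediction models from global (whole-organ) medical image features rather
    than segmented tumors. Implements bilateral mammographic asymmetry
    features, emphysema quantification and gray-level co-occurrence texture
    from lung CT, visceral and subcutaneous adiposity segmentation from
    abdominal CT, and global kinetic enhancement statistics from paired
    pre/post contrast breast MRI. Provides a distance-weighted
    k-nearest-neighbour risk score, SMOTE minority oversampling and
    correlation-based feature selection embedded inside leave-one-case-out
    cross-validation, and the downstream evaluation statistics: ROC AUC,
    confusion matrices at a fixed operating threshold, quantile-subgroup
    odds-ratio tables with Woolf confidence intervals, and the
    Cochran-Armitage trend test. Synthetic phantom generators with known
    ground truth make every stage testable without patient data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    purrr,
    rlang,
    ggplot2,
    readr,
    jsonlite,
    withr,
    generics,
    RNifti,
    png,
    tiff,
    randomForest,
    e1071,
    nnet
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
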