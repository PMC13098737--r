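Package: ramanfcd
Title: Single-Cell Raman Microspectroscopy Classification of Focal
    Cortical Dysplasia
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: End-to-end analysis of single-cell Raman microspectra for
    discriminating focal cortical dysplasia (FCD) type II cells from
    normal cortical neurons, and FCD subtype IIa from IIb. Provides the
    full preprocessing chain (dark-count subtraction, instrument response
    correction, wavenumber calibration, Savitzky-Golay smoothing,
    rolling-ball baseline removal, axis truncation, standard normal
    variate normalization), Gaussian peak-fit feature extraction with a
    dataset-wide consensus peak set, L1-based feature selection with a
    cross-validated linear support vector machine, and ROC evaluation at
    the upper-left operating point. A forward model of the acquisition
    (class-dependent Raman bands on an autofluorescence baseline with
    CCD noise and instrument distortions) generates synthetic datasets
    and matching calibration references so every stage is testable
    without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    e1071,
    glmnet,
    jsonlite,
    minpack.lm,
    stats,
    tools,
    utils
Suggests:
    pROC,
    signal,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
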