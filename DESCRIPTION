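Package: sleepscan
Title: Information Extraction from Scanned Sleep-Study Reports
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A scanned-document information-extraction pipeline for
    polysomnography (sleep study) reports: image preprocessing
    (gray-scaling, one-iteration dilate/erode, contrast gain), word-level
    OCR adapters with synthetic engine-free backends, deidentification of
    patient names, record numbers and dates, numeric-candidate
    segmentation with 21-word context windows and layout features,
    bag-of-words and dual-branch neural classifiers (BiLSTM with
    corpus-trained CBOW embeddings, or a pluggable transformer encoder),
    and document-level value extraction of the apnea-hypopnea index (AHI)
    and minimum oxygen saturation (SaO2) with AUROC/DeLong and
    chi-squared model comparison. Includes a seeded synthetic report
    generator so the whole pipeline is testable without protected health
    information.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils,
    glmnet,
    e1071,
    ranger,
    nnet,
    caret,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    EBImage,
    png,
    withr
Config/testthat/edition: 3
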