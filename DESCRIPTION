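Package: radstrat
Title: Radiomics-Based Two-Class Cancer Risk Stratification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested, reusable pipeline for radiomics-driven risk
    stratification of tumours from paired-modality 2D regions of interest.
    Extracts 55 texture features per modality (histogram, gray-level
    co-occurrence matrix, gray-level difference matrix and Fourier spectrum
    families; 110 per patient), benchmarks seven classification algorithms
    under random oversampling and repeated stratified cross-validation,
    selects the best learner by Friedman-Nemenyi rank analysis, trains a
    final classifier with an averaged maximum-F-measure decision threshold,
    and validates it on an independent cohort against an ordinal reader-score
    comparator, a label-permutation null and a paired bootstrap comparison.
    Includes a seeded synthetic-cohort generator (correlated random-field
    textures, binary risk labels, ordinal reader scores) so the entire
    pipeline is exercisable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    e1071,
    glmnet,
    randomForest,
    jsonlite,
    png,
    tiff
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
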