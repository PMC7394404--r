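Package: missvote
Title: Missense Variant Deleteriousness Prediction with a Soft-Voting Ensemble
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts the deleteriousness of missense variants with a weighted
    soft-voting ensemble of a random forest and a logistic regression trained
    on a 113-feature panel spanning multi-ethnic minor allele frequencies,
    evolutionary conservation, amino-acid substitution properties and component
    predictor scores. Includes the dataset-construction filter cascade
    (clinical-significance, review-status, frequency, depth and circularity
    filters), recursive feature elimination, a confusion-matrix metric panel
    (sensitivity, specificity, MCC, AUC, log loss, diagnostic odds ratio and
    more), repeated balanced evaluation over minor-allele-frequency bins, a
    spike-in disease-exome simulator for causative-variant ranking, and a
    synthetic-data generator emulating the statistical structure of curated
    clinical and population variant databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    randomForest,
    vcfR,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite,
    optparse,
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
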