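Package: ki67score
Title: Selection-Bias-Free Automated Ki67 Scoring with Emergent Hot Spots
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automated scoring of Ki67 proliferation from brightfield
    immunohistochemistry images of breast tumors. The whole annotated tumor
    region is unmixed into hematoxylin and DAB optical densities, nuclei are
    detected and classified, and the region is partitioned into 500x500
    micron tiles so that proliferation hot spots emerge as the top-scoring
    tiles rather than being hand-picked. Includes agreement statistics
    (Pearson r, Lin's concordance correlation coefficient), Oncotype DX
    risk-group assignment and confusion summaries, a random-forest
    cross-validation harness with permutation variable importance for
    predicting Recurrence Scores from clinico-pathological data, and
    generators for synthetic slides and cohorts with ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    readr,
    jsonlite,
    stats,
    generics,
    randomForest,
    EBImage,
    png,
    tiff
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
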