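Package: phossite
Title: Sequence-Based Prediction of Protein Phosphorylation Sites
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Train, evaluate and apply sequence-based predictors of protein
    phosphorylation sites (phospho-serine, -threonine and -tyrosine), with an
    emphasis on rice proteomes. Extracts 25-residue windows around candidate
    S/T/Y residues, encodes them by amino-acid occurrence frequency (AF),
    composition of k-spaced amino-acid pairs (CKSAAP) and nearest-neighbour
    distance ratios under a normalized BLOSUM62 similarity (KNN), reduces
    combined encodings with relief-F feature weighting, and fits SVM (RBF
    kernel), random-forest, decision-tree and k-nearest-neighbour classifiers.
    Includes stratified 10-fold cross-validation with sensitivity,
    specificity, accuracy, Matthews correlation and ROC/AUC reporting, a
    synthetic fragment generator with plantable positional and paired motifs,
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    class,
    dplyr,
    e1071,
    generics,
    ggplot2,
    randomForest,
    readr,
    rlang,
    rpart,
    stats,
    tibble,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
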