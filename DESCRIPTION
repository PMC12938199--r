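Package: ppigray
Title: Protein-Protein Interaction Prediction from Grayscale Feature Maps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Sequence-based prediction of protein-protein interactions.
    Four feature families are extracted per protein: amphiphilic pseudo
    amino acid composition (APAAC), segmented same-residue interval-distance
    statistics, PSSM-derived evolutionary conservation descriptors, and
    coding-sequence descriptors including a unit-circle nucleotide mapping.
    The 576 features of each protein are arranged into a 36 x 16 matrix;
    a protein pair is encoded as a min-max normalized 36 x 32 grayscale
    map and classified by an ensemble of five small convolutional networks
    trained on balanced undersampled training sets. Includes readers for
    FASTA, PSI-BLAST ASCII PSSM, pair and localization tables, a synthetic
    fixture generator with a planted interaction signal, dataset
    construction with subcellular-localization negative sampling,
    evaluation metrics (ROC/AUC, PR/AUPR, top-u precision, MCC), and
    thresholded interaction/non-interaction network prediction.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Rcpp,
    Biostrings,
    png,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    jsonlite
Config/testthat/edition: 3
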