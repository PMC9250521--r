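Package: nvdt
Title: Protein-Protein Interaction and Non-Interaction Prediction from Gene
    Sequence Natural Vectors
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Sequence-based prediction of protein-protein interactions (PPI)
    and non-interactions (PPNI) from coding (CDS) nucleotide sequences. Each
    gene sequence is summarised by a 92-dimensional natural vector: per-base
    counts, mean positions and second normalized central moments of the four
    nucleotides, plus 16 dinucleotide and 64 trinucleotide counts. Protein
    pairs are encoded under five combination schemes (absolute difference,
    sum, difference plus sum, elementwise product, concatenation), Z-score
    standardized with training-set statistics, and classified with a
    radial-basis SVM or a random forest. Includes the full evaluation metric
    suite (accuracy, precision, sensitivity, specificity, MCC, F1, AUC),
    k-fold cross-validation with mean and standard deviation reporting,
    dataset construction utilities (length and redundancy filtering, balanced
    negative sampling, 5:1 splits), non-interaction network prediction with
    incremental retraining and Pajek export, and a synthetic CDS generator
    with a planted codon-usage signal for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    e1071,
    randomForest,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
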