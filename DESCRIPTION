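Package: bepiscan
Title: Sequence Similarity Based Prediction of Linear B Cell Epitopes
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Predicts linear B cell epitopes by sequence similarity to a
    database of experimentally verified epitope peptides. A peptide query is
    called an epitope when an exhaustive ungapped alignment search against the
    database yields a hit of length >= 8 residues and identity >= 80%. Protein
    queries are scanned for hits, per-residue hit tallies are normalized into
    z-scores, and non-overlapping epitope cores of 8+ residues are extracted
    and annotated with BLOSUM62 bit scores, neutralizing-antibody support and
    averaged accessibility/flexibility tracks. The package also provides the
    dataset-construction toolkit (length filtering, greedy redundancy
    reduction, composition statistics, random-peptide generation) and the
    k-fold cross-validation harness (sensitivity, specificity, accuracy,
    Matthews correlation coefficient) used to validate the approach.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    S4Vectors,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
biocViews: Alignment, Epitope, SequenceMatching, Classification
RoxygenNote: 7.3.3
Collate:
    'RcppExports.R'
    'AllClasses.R'
    'blosum.R'
    'io.R'
    'curation.R'
    'stats.R'
    'simulate.R'
    'align.R'
    'search.R'
    'predict.R'
    'cores.R'
    'evaluate.R'
    'bundle.R'
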