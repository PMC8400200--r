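Package: moonpep
Title: Classifier-Guided Design of Moonlighting Cell-Penetrating Peptides
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to featurize peptide sequences with 27 physicochemical
    descriptors (residue composition, Henderson-Hasselbalch charge,
    isoelectric point, sliding-window charge and hydrophobic-moment ranges,
    octanol-water partition and helix-former content), to train a random
    forest that scores the probability that a sequence behaves as a
    cell-penetrating peptide (CPP), and to design "moonlighting" peptides by
    a constrained residue-addition search: embedding a functional motif
    inside a CPP, or silencing a CPP core inside a non-CPP until proteolytic
    activation. Includes a synthetic labeled-dataset generator with CPP-like
    statistical structure so the full pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    jsonlite,
    Biostrings,
    S4Vectors
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    seqinr,
    randomForest,
    yaml,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'utils.R'
    'scales.R'
    'peptides.R'
    'descriptors.R'
    'forest.R'
    'archive.R'
    'design.R'
    'synthetic.R'
    'cli.R'
    'moonpep-package.R'
    'RcppExports.R'
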