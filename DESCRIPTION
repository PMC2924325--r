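Package: riboSnitch
Title: Quantifying SNP-Induced Perturbation of RNA Structural Ensembles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects riboSNitches: single-nucleotide variants that
    reorganise the Boltzmann ensemble of RNA secondary structures.
    Computes base-pair probability matrices from an exact nested-structure
    partition function (McCaskill-style inside-outside dynamic programming
    over a simplified nearest-neighbour energy model), scores a variant by
    the Pearson correlation of wild-type and mutant per-nucleotide pairing
    probabilities, assigns significance by exhaustive scanning of all 3n
    single-nucleotide substitutions (rank-based empirical p-value), and
    characterises the nature of an ensemble shift by Boltzmann stochastic
    sampling followed by principal-component projection and clustering of
    binary base-pairing vectors. Includes an exhaustive enumeration oracle
    for validation, deterministic fixture generators (random sequences,
    designed hairpins, two-state switch constructs), and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    Biostrings,
    jsonlite
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'structure.R'
    'energy-model.R'
    'thermo.R'
    'snpfold.R'
    'oracle.R'
    'fixtures.R'
    'ensemble.R'
    'rna-sequence.R'
    'io.R'
    'cli.R'
    'utils.R'
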