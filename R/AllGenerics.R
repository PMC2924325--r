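#' @include AllClasses.R
NULL

#' Per-nucleotide pairing probability (accessibility vector)
#'
#' Column sums of a base-pair probability matrix: element k is the
#' ensemble probability that residue k is paired with any partner.
#'
#' @param x a [BasePairProbMatrix] (or plain symmetric matrix).
#' @return numeric vector of length n with values in [0, 1].
#' @export
setGeneric("accessibility", function(x) standardGeneric("accessibility"))

#' Base pairs of a structure
#' @param x object holding base pairs.
#' @return two-column integer matrix (i, j), 1-based, i < j.
#' @export
setGeneric("basePairs", function(x) standardGeneric("basePairs"))

#' Pairing probability matrix
#' @param x a [BasePairProbMatrix].
#' @return the n x n probability matrix.
#' @export
setGeneric("pairingProbabilities",
           function(x) standardGeneric("pairingProbabilities"))

#' Log partition value
#' @param x a [BasePairProbMatrix].
#' @return log Z.
#' @export
setGeneric("logPartition", function(x) standardGeneric("logPartition"))

#' Sequence identifier
#' @param x an object with a sequence identifier.
#' @return character scalar.
#' @export
setGeneric("seqId", function(x) standardGeneric("seqId"))

#' Residue string
#' @param x an [RnaSequence] (or object holding one).
#' @return character scalar over A, C, G, U.
#' @export
setGeneric("residues", function(x) standardGeneric("residues"))

#' Sampled structures
#' @param x an [EnsembleSample].
#' @return list of [SecondaryStructure] objects.
#' @export
setGeneric("structures", function(x) standardGeneric("structures"))

#' Cluster occupancy fractions
#' @param x a [ClusterSummary].
#' @return sequences x clusters matrix of fractions.
#' @export
setGeneric("occupancy", function(x) standardGeneric("occupancy"))

#' Scan correlation table
#' @param x a [MutationScanResult].
#' @return data.frame with one row per scanned mutation.
#' @export
setGeneric("correlations", function(x) standardGeneric("correlations"))

#' Dot-bracket rendering
#' @param x a [SecondaryStructure].
#' @return character scalar in dot-bracket notation.
#' @export
setGeneric("toDotBracket", function(x) standardGeneric("toDotBracket"))
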