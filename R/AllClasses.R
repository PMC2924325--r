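#' @import methods
#' @importFrom Rcpp sourceCpp
#' @useDynLib riboSnitch, .registration = TRUE
NULL

RNA_BASES <- c("A", "C", "G", "U")
CANONICAL_PAIRS <- c("AU", "UA", "GC", "CG", "GU", "UG")

#' RNA sequence with identifier
#'
#' A validated single-stranded RNA sequence. DNA input is accepted by the
#' constructors (T is normalised to U); ambiguity codes are rejected.
#'
#' @slot id sequence identifier.
#' @slot residues character scalar over the alphabet A, C, G, U.
#' @export
setClass("RnaSequence",
  representation(id = "character", residues = "character"))

setValidity("RnaSequence", function(object) {
  if (length(object@id) != 1L) return("id must be a single string")
  if (length(object@residues) != 1L || nchar(object@residues) < 1L)
    return("residues must be a non-empty string")
  bad <- regmatches(object@residues,
                    regexpr("[^ACGU]", object@residues))
  if (length(bad) > 0L) {
    off <- regexpr("[^ACGU]", object@residues)
    return(sprintf("illegal residue '%s' at position %d in record '%s'",
                   bad, off, object@id))
  }
  TRUE
})

#' Simplified nearest-neighbour energy model
#'
#' Thermodynamic parameters for nested RNA secondary structures: stacking
#' energies per adjacent pair step, length-dependent hairpin, bulge and
#' interior-loop penalties (Jacobson-Stockmayer log extrapolation beyond
#' the tables), and a linear multiloop model. All energies in kcal/mol.
#'
#' @slot allowedPairs unordered residue pairs that may form.
#' @slot stack 6x6 matrix, rows = outer pair (i,j), cols = inner pair
#'   (i+1,j-1), dimnames over [allowedPairs].
#' @slot hairpin,bulge,internal numeric vectors of loop penalties indexed
#'   by loop length (names are lengths).
#' @slot multiloopOffset,multiloopBranch,multiloopUnpaired linear
#'   multiloop coefficients.
#' @slot minHairpin minimum unpaired bases in a hairpin loop (>= 3).
#' @slot maxInteriorUnpaired cap on total unpaired bases in a bulge or
#'   interior loop; larger loops are excluded from the ensemble.
#' @slot extrapolationCoeff coefficient of the R*T*log(l/Lmax) loop-length
#'   extrapolation.
#' @slot temperature kelvin.
#' @slot gasConstant kcal/(mol*K).
#' @slot version parameter-set version string.
#' @slot digest md5 digest of the canonical parameter text.
#' @export
setClass("EnergyModel",
  representation(allowedPairs = "character", stack = "matrix",
    hairpin = "numeric", bulge = "numeric", internal = "numeric",
    multiloopOffset = "numeric", multiloopBranch = "numeric",
    multiloopUnpaired = "numeric", minHairpin = "integer",
    maxInteriorUnpaired = "integer", extrapolationCoeff = "numeric",
    temperature = "numeric", gasConstant = "numeric",
    version = "character", digest = "character"))

setValidity("EnergyModel", function(object) {
  if (!all(object@allowedPairs %in% CANONICAL_PAIRS))
    return("allowedPairs must be a subset of AU, UA, GC, CG, GU, UG")
  if (object@minHairpin < 3L) return("minHairpin must be >= 3")
  vals <- c(object@stack, object@hairpin, object@bulge, object@internal,
            object@multiloopOffset, object@multiloopBranch,
            object@multiloopUnpaired)
  if (any(!is.finite(vals))) return("all energies must be finite")
  if (object@temperature <= 0 || object@gasConstant <= 0)
    return("temperature and gas constant must be positive")
  TRUE
})

#' One nested secondary structure
#'
#' @slot pairs two-column integer matrix of base pairs, 1-based, i < j.
#' @slot n sequence length.
#' @export
setClass("SecondaryStructure",
  representation(pairs = "matrix", n = "integer"))

setValidity("SecondaryStructure", function(object) {
  p <- object@pairs
  if (ncol(p) != 2L) return("pairs must have two columns")
  if (nrow(p) == 0L) return(TRUE)
  if (any(p < 1L) || any(p > object@n)) return("pair index out of range")
  if (any(p[, 1] >= p[, 2])) return("pairs must satisfy i < j")
  if (anyDuplicated(as.vector(p))) return("a residue appears in two pairs")
  o <- order(p[, 1])
  op <- p[o, , drop = FALSE]
  # nestedness: no crossing pairs
  if (nrow(op) > 1L) {
    for (r in seq_len(nrow(op) - 1L)) {
      later <- op[(r + 1L):nrow(op), , drop = FALSE]
      inside <- later[, 1] < op[r, 2]
      if (any(inside & later[, 2] > op[r, 2]))
        return("crossing (pseudoknotted) pairs are not admissible")
    }
  }
  TRUE
})

#' Base-pair probability matrix
#'
#' Ensemble probabilities P(i,j) that residues i and j are paired, with
#' the log partition value. Symmetric; rows sum to at most one.
#'
#' @slot probs n x n numeric matrix.
#' @slot logZ natural log of the partition value Z (Z >= 1 because the
#'   open chain contributes weight exp(0) = 1).
#' @slot seqId identifier of the source sequence.
#' @export
setClass("BasePairProbMatrix",
  representation(probs = "matrix", logZ = "numeric", seqId = "character"))

setValidity("BasePairProbMatrix", function(object) {
  P <- object@probs
  if (nrow(P) != ncol(P)) return("probability matrix must be square")
  if (any(P < 0) || any(P > 1)) return("entries must lie in [0, 1]")
  if (max(abs(P - t(P))) > 1e-12) return("matrix must be symmetric")
  if (any(rowSums(P) > 1 + 1e-9))
    return("row sums must not exceed 1 (a base pairs with at most one partner)")
  if (object@logZ < -1e-12) return("Z must be >= 1")
  TRUE
})

#' Boltzmann-sampled structure ensemble
#'
#' @slot pairsList list of two-column pair matrices, one per draw.
#' @slot n sequence length.
#' @slot seed integer seed that produced the sample.
#' @slot count number of draws.
#' @slot label sequence label.
#' @export
setClass("EnsembleSample",
  representation(pairsList = "list", n = "integer", seed = "integer",
                 count = "integer", label = "character"))

setValidity("EnsembleSample", function(object) {
  if (length(object@pairsList) != object@count)
    return("count must equal the number of stored structures")
  TRUE
})

#' Single-nucleotide substitution
#'
#' @slot position 1-based position.
#' @slot wild,variant residues in A, C, G, U; wild != variant.
#' @export
setClass("Mutation",
  representation(position = "integer", wild = "character",
                 variant = "character"))

setValidity("Mutation", function(object) {
  if (!(object@wild %in% RNA_BASES) || !(object@variant %in% RNA_BASES))
    return("wild and variant bases must be A, C, G or U")
  if (object@wild == object@variant)
    return("wild and variant bases must differ")
  if (object@position < 1L) return("position must be >= 1")
  TRUE
})

#' Exhaustive single-mutation scan
#'
#' Correlation of wild-type and mutant accessibility vectors for all 3n
#' substitutions of a sequence, plus the 4 x n heat-map layout in which
#' wild-type cells carry NA.
#'
#' @slot seqId source sequence identifier.
#' @slot n sequence length.
#' @slot table data.frame: mutation, position, wild, variant, correlation.
#' @slot heatmap 4 x n matrix (rows A, C, G, U); NA marks wild-type cells.
#' @slot engine engine that produced the scan.
#' @slot paramDigest digest of the energy parameters used.
#' @export
setClass("MutationScanResult",
  representation(seqId = "character", n = "integer", table = "data.frame",
                 heatmap = "matrix", engine = "character",
                 paramDigest = "character"))

setValidity("MutationScanResult", function(object) {
  if (nrow(object@table) != 3L * object@n)
    return("a scan must contain exactly 3n mutations")
  if (any(object@table$correlation > 1 + 1e-12))
    return("correlations cannot exceed 1")
  TRUE
})

#' Scored SNP with empirical p-value
#'
#' @slot mutation the scored [Mutation].
#' @slot correlation Pearson r of WT and mutant accessibility vectors.
#' @slot rank tie-inclusive rank of the correlation among all 3n scanned
#'   mutations (number with r <= r(target), self included).
#' @slot pValue rank / 3n.
#' @slot total total number of scanned mutations, 3n.
#' @export
setClass("SnpScore",
  representation(mutation = "Mutation", correlation = "numeric",
                 rank = "integer", pValue = "numeric", total = "integer"))

setValidity("SnpScore", function(object) {
  if (object@rank < 1L || object@rank > object@total)
    return("rank must lie in [1, 3n]")
  if (abs(object@pValue - object@rank / object@total) > 1e-12)
    return("p-value must equal rank / 3n")
  TRUE
})

#' Shared principal-component basis over structure bit vectors
#'
#' @slot rotation n x 2 loading matrix (deterministic sign convention:
#'   the largest-magnitude loading of each component is positive).
#' @slot center pooled-subsample mean bit vector used for centering.
#' @slot explainedVar variances of the two components.
#' @slot provenance list: labels of contributing sequences, subsample
#'   size and seed.
#' @export
setClass("PcaBasis",
  representation(rotation = "matrix", center = "numeric",
                 explainedVar = "numeric", provenance = "list"))

#' Projection of a sampled ensemble onto a shared basis
#'
#' @slot label sequence label.
#' @slot coords m x 2 matrix of (PC1, PC2) scores, one row per structure.
#' @slot provenance basis provenance, carried along.
#' @export
setClass("PcaProjection",
  representation(label = "character", coords = "matrix",
                 provenance = "list"))

#' Cluster occupancy of structural ensembles
#'
#' @slot k number of clusters.
#' @slot occupancy sequences x clusters matrix of fractions (rows sum to 1).
#' @slot assignments list of per-sequence integer cluster assignments.
#' @slot representatives data.frame: cluster, label, structureIndex, pc1,
#'   pc2 - the sampled structure nearest each centroid.
#' @slot assignmentRule descriptor of the clustering rule.
#' @export
setClass("ClusterSummary",
  representation(k = "integer", occupancy = "matrix",
                 assignments = "list", representatives = "data.frame",
                 assignmentRule = "character"))

setValidity("ClusterSummary", function(object) {
  if (any(abs(rowSums(object@occupancy) - 1) > 1e-9))
    return("per-sequence occupancies must sum to 1")
  TRUE
})

#' Designed two-state switch construct
#'
#' A short sequence with two mutually exclusive helices, a designated
#' toggling mutation that disrupts the dominant helix, and a designated
#' neutral mutation in the unpaired tail. Certified against the
#' enumeration oracle at construction time.
#'
#' @slot sequence the [RnaSequence].
#' @slot helixA,helixB two-column pair matrices of the competing helices.
#' @slot toggling,neutral the designated [Mutation]s.
#' @slot pHelixA oracle-computed ensemble probability that every helix-A
#'   pair is simultaneously formed in the wild type.
#' @export
setClass("SwitchDesign",
  representation(sequence = "RnaSequence", helixA = "matrix",
                 helixB = "matrix", toggling = "Mutation",
                 neutral = "Mutation", pHelixA = "numeric"))

#' Run configuration (see [runConfig()])
#'
#' @slot engine engine selector, "internal" or "external".
#' @slot paramsPath energy-parameter file path (NA = bundled default).
#' @slot seeds named integer vector of explicit seeds.
#' @slot samples,basisSubsample,k sample sizes and cluster count.
#' @slot outDir output directory.
#' @slot logLevel logging threshold.
#' @export
setClass("RunConfig",
  representation(engine = "character", paramsPath = "character",
                 seeds = "integer", samples = "integer",
                 basisSubsample = "integer", k = "integer",
                 outDir = "character", logLevel = "character"))
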