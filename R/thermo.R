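#' @include AllClasses.R AllGenerics.R energy-model.R structure.R
NULL

.engineRegistry <- new.env(parent = emptyenv())

#' Register an external folding engine
#'
#' The scoring method is engine-agnostic: any backend that returns a
#' base-pair probability matrix can stand behind [partitionFunction()].
#' An adapter is a function `function(seq, model)` returning a
#' [BasePairProbMatrix]. See [viennaRnaEngine()] for a ready-made
#' adapter around the ViennaRNA `RNAfold` executable.
#'
#' @param fn adapter function, or NULL to unregister.
#' @return invisibly, the previously registered adapter (or NULL).
#' @export
registerExternalEngine <- function(fn) {
  old <- .engineRegistry$external
  .engineRegistry$external <- fn
  invisible(old)
}

#' Partition function and base-pair probabilities
#'
#' Computes the Boltzmann ensemble of all nested secondary structures by
#' McCaskill-style inside-outside dynamic programming in O(n^3) time:
#' the partition value Z = sum over structures of exp(-E/RT) (the open
#' chain contributes exp(0) = 1, so Z >= 1) and the matrix of pairing
#' probabilities P(i,j) = sum over structures containing (i,j) of
#' exp(-E/RT)/Z.
#'
#' @param seq an [RnaSequence] (or coercible).
#' @param model an [EnergyModel].
#' @param engine "internal" for the built-in engine, "external" for the
#'   adapter registered with [registerExternalEngine()].
#' @return a [BasePairProbMatrix].
#' @examples
#' bppm <- partitionFunction(designHairpin(3, 3))
#' accessibility(bppm)
#' @export
partitionFunction <- function(seq, model = defaultEnergyModel(),
                              engine = c("internal", "external")) {
  engine <- match.arg(engine)
  seq <- rnaSequence(seq)
  if (engine == "external") {
    fn <- .engineRegistry$external
    if (is.null(fn))
      stop("no external engine registered; see registerExternalEngine()")
    return(fn(seq, model))
  }
  out <- .cPartition(.resCodes(seq), .modelTables(model, length(seq)))
  new("BasePairProbMatrix", probs = out$probs,
      logZ = max(out$logZ, 0), seqId = seqId(seq))
}

#' @rdname pairingProbabilities
#' @export
setMethod("pairingProbabilities", "BasePairProbMatrix",
          function(x) x@probs)

#' @rdname logPartition
#' @export
setMethod("logPartition", "BasePairProbMatrix", function(x) x@logZ)

#' @rdname seqId
#' @export
setMethod("seqId", "BasePairProbMatrix", function(x) x@seqId)

#' @describeIn partitionFunction sequence length of the matrix.
#' @export
setMethod("length", "BasePairProbMatrix", function(x) nrow(x@probs))

setMethod("show", "BasePairProbMatrix", function(object) {
  cat(sprintf(paste0(
    "BasePairProbMatrix '%s' (%d nt)\n",
    "  log Z = %.4f; %d entries above 0.01\n"),
    object@seqId, nrow(object@probs), object@logZ,
    sum(object@probs[upper.tri(object@probs)] > 0.01)))
})

#' @rdname accessibility
#' @export
setMethod("accessibility", "BasePairProbMatrix",
          function(x) colSums(x@probs))

#' @rdname accessibility
#' @export
setMethod("accessibility", "matrix", function(x) colSums(x))

#' Minimum free energy structure
#'
#' Zuker-style dynamic programming over the same energy terms as
#' [partitionFunction()]. Ties are broken by a deterministic traceback
#' (hairpin first, then interior loops by ascending inner pair, then
#' multiloop splits in ascending order).
#'
#' @inheritParams partitionFunction
#' @return list with elements `structure` (a [SecondaryStructure]) and
#'   `energy` (kcal/mol; 0 for a sequence that cannot pair).
#' @export
mfeStructure <- function(seq, model = defaultEnergyModel()) {
  seq <- rnaSequence(seq)
  out <- .cMfe(.resCodes(seq), .modelTables(model, length(seq)))
  list(structure = secondaryStructure(out$pairs, length(seq)),
       energy = out$energy)
}

#' Boltzmann stochastic traceback sampling
#'
#' Draws structures i.i.d. with probability exp(-E/RT)/Z by stochastic
#' traceback through the partition-function matrices. The random number
#' stream is R's Mersenne-Twister; the seed is applied locally (the
#' caller's RNG state is restored) and recorded in the result, so an
#' identical (sequence, model, count, seed) call reproduces the
#' identical sample.
#'
#' @inheritParams partitionFunction
#' @param count number of structures to draw (>= 1).
#' @param seed integer seed.
#' @return an [EnsembleSample].
#' @export
sampleStructures <- function(seq, model = defaultEnergyModel(),
                             count, seed) {
  seq <- rnaSequence(seq)
  stopifnot(count >= 1L)
  draws <- withSeed(as.integer(seed),
    .cSample(.resCodes(seq), .modelTables(model, length(seq)),
             as.integer(count)))
  new("EnsembleSample", pairsList = draws, n = length(seq),
      seed = as.integer(seed), count = as.integer(count),
      label = seqId(seq))
}

#' @rdname structures
#' @export
setMethod("structures", "EnsembleSample", function(x)
  lapply(x@pairsList, secondaryStructure, n = x@n))

#' @describeIn sampleStructures number of sampled structures.
#' @export
setMethod("length", "EnsembleSample", function(x) x@count)

#' @describeIn sampleStructures extract one draw as a
#'   [SecondaryStructure].
#' @param i draw index.
#' @export
setMethod("[[", "EnsembleSample", function(x, i)
  secondaryStructure(x@pairsList[[i]], x@n))

setMethod("show", "EnsembleSample", function(object) {
  cat(sprintf(
    "EnsembleSample '%s': %d structures of %d nt (seed %d)\n",
    object@label, object@count, object@n, object@seed))
})

#' ViennaRNA external-engine adapter
#'
#' Builds an adapter around the `RNAfold` executable (Turner parameters)
#' for use with `engine = "external"`; with it the absolute correlation
#' values of the full-parameter model can be reproduced. The adapter
#' shells out to `RNAfold -p` and parses the pair probabilities from the
#' PostScript dot plot. Requires ViennaRNA on the PATH; the internal
#' engine and all package tests do not depend on it.
#'
#' @param exe path to the RNAfold executable.
#' @return an adapter function suitable for [registerExternalEngine()].
#' @export
viennaRnaEngine <- function(exe = Sys.which("RNAfold")) {
  force(exe)
  function(seq, model) {
    if (!nzchar(exe)) stop("RNAfold executable not found")
    seq <- rnaSequence(seq)
    dir <- tempfile("vrna")
    dir.create(dir)
    on.exit(unlink(dir, recursive = TRUE), add = TRUE)
    fa <- file.path(dir, "in.fa")
    writeLines(c(">q", residues(seq)), fa)
    oldwd <- setwd(dir)  # RNAfold writes the dot plot into the cwd
    on.exit(setwd(oldwd), add = TRUE, after = FALSE)
    out <- system2(exe, c("-p", "--noPS", "-i", shQuote(fa)),
                   stdout = TRUE, stderr = FALSE)
    ps <- file.path(dir, "q_dp.ps")
    if (!file.exists(ps)) stop("RNAfold did not produce a dot plot")
    lines <- grep("ubox$", readLines(ps), value = TRUE)
    lines <- grep("^[0-9]+ [0-9]+ [0-9.eE+-]+ ubox$", lines, value = TRUE)
    n <- length(seq)
    P <- matrix(0, n, n)
    for (ln in lines) {
      f <- strsplit(ln, " ", fixed = TRUE)[[1]]
      i <- as.integer(f[1]); j <- as.integer(f[2])
      p <- as.numeric(f[3])^2  # ubox stores sqrt(p)
      P[i, j] <- p; P[j, i] <- p
    }
    # the ensemble free energy is printed in square brackets
    fe <- grep("\\[ *-?[0-9.]+\\]", out, value = TRUE)
    logZ <- if (length(fe) >= 1L) {
      g <- as.numeric(sub(".*\\[ *(-?[0-9.]+)\\].*", "\\1", fe[1]))
      -g / thermalEnergy(model)
    } else 0
    new("BasePairProbMatrix", probs = P, logZ = max(logZ, 0),
        seqId = seqId(seq))
  }
}
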