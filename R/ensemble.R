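#' @include AllClasses.R AllGenerics.R thermo.R snpfold.R
NULL

#' Bit-vector matrix of a sampled ensemble
#'
#' @param sample an [EnsembleSample].
#' @return count x n matrix of 0/1 (1 = residue paired).
#' @export
structureVectors <- function(sample) {
  stopifnot(is(sample, "EnsembleSample"))
  n <- sample@n
  out <- matrix(0L, sample@count, n)
  for (r in seq_len(sample@count)) {
    p <- sample@pairsList[[r]]
    if (length(p) > 0L) out[r, as.vector(p)] <- 1L
  }
  out
}

#' Build a shared principal-component basis
#'
#' Pools a seeded random subsample (default 1000 structures per
#' sequence) of the bit vectors of several sampled ensembles,
#' mean-centres them (no variance scaling: the bits are homoscedastic
#' by construction) and eigen-decomposes the covariance. The top two
#' components, with a deterministic sign convention (the
#' largest-magnitude loading of each component is positive), form the
#' common coordinate system onto which all compared sequences are
#' projected.
#'
#' @param samples list of [EnsembleSample]s over sequences of equal
#'   length.
#' @param subsample structures drawn per sequence for the basis; if an
#'   ensemble is smaller, all of it is used with a warning.
#' @param seed integer seed for the subsampling.
#' @return a [PcaBasis].
#' @export
buildSharedBasis <- function(samples, subsample = 1000L, seed) {
  stopifnot(is.list(samples), length(samples) >= 1L)
  lens <- vapply(samples, slot, integer(1), "n")
  if (length(unique(lens)) != 1L)
    stop("all ensembles must come from sequences of equal length")
  pooled <- withSeed(as.integer(seed), {
    do.call(rbind, lapply(samples, function(s) {
      bits <- structureVectors(s)
      m <- nrow(bits)
      if (m < subsample) {
        warning("ensemble '", s@label, "' has only ", m,
                " structures; using all of them for the basis")
        bits
      } else bits[sample.int(m, subsample), , drop = FALSE]
    }))
  })
  ctr <- colMeans(pooled)
  pc <- stats::prcomp(pooled, center = TRUE, scale. = FALSE)
  if (length(pc$sdev) < 2L || pc$sdev[2]^2 < 1e-18) {
    if (length(pc$sdev) < 1L || pc$sdev[1]^2 < 1e-18)
      stop("pooled subsample has (near-)zero variance; ",
           "both components are degenerate")
    stop("second principal component is degenerate ",
         "(pooled variance concentrated on one axis or absent)")
  }
  rot <- pc$rotation[, 1:2, drop = FALSE]
  for (k in 1:2) {
    lead <- which.max(abs(rot[, k]))
    if (rot[lead, k] < 0) rot[, k] <- -rot[, k]
  }
  colnames(rot) <- c("PC1", "PC2")
  new("PcaBasis", rotation = rot, center = ctr,
      explainedVar = pc$sdev[1:2]^2,
      provenance = list(
        labels = vapply(samples, slot, character(1), "label"),
        subsample = as.integer(subsample), seed = as.integer(seed)))
}

setMethod("show", "PcaBasis", function(object) {
  cat(sprintf(paste0(
    "PcaBasis over %d nt (subsample %d per sequence, seed %d)\n",
    "  component variances %.4f, %.4f; sequences: %s\n"),
    nrow(object@rotation), object@provenance$subsample,
    object@provenance$seed, object@explainedVar[1],
    object@explainedVar[2],
    paste(object@provenance$labels, collapse = ", ")))
})

#' Project a sampled ensemble onto a shared basis
#'
#' Coordinates are the centred bit vectors times the component
#' loadings; because every compared sequence uses the same basis,
#' proximity in the plane reflects similarity in structure space.
#'
#' @param sample an [EnsembleSample].
#' @param basis a [PcaBasis] built over the same sequence length.
#' @param label label for the projection (defaults to the sample's).
#' @return a [PcaProjection].
#' @export
projectSample <- function(sample, basis, label = sample@label) {
  stopifnot(is(sample, "EnsembleSample"), is(basis, "PcaBasis"))
  bits <- structureVectors(sample)
  if (ncol(bits) != nrow(basis@rotation))
    stop("sequence length ", ncol(bits),
         " does not match the basis dimension ", nrow(basis@rotation))
  coords <- sweep(bits, 2L, basis@center) %*% basis@rotation
  colnames(coords) <- c("PC1", "PC2")
  new("PcaProjection", label = label, coords = coords,
      provenance = basis@provenance)
}

setMethod("show", "PcaProjection", function(object) {
  cat(sprintf(
    "PcaProjection '%s': %d structures; PC1 in [%.3f, %.3f]\n",
    object@label, nrow(object@coords), min(object@coords[, 1]),
    max(object@coords[, 1])))
})

#' Cluster occupancy of projected ensembles
#'
#' Fits seeded k-means (50 restarts) on the pooled projections of all
#' sequences, then reports, per sequence, the fraction of its sampled
#' structures assigned to each cluster - a reproducible surrogate for
#' reading clusters off the projection plane by eye. Clusters are
#' relabelled in decreasing order of pooled size so that labels are
#' stable across runs.
#'
#' @param projections list of [PcaProjection]s on one shared basis.
#' @param k number of clusters (default 3).
#' @param seed integer seed for the k-means restarts.
#' @return a [ClusterSummary]; its `representatives` slot names the
#'   sampled structure nearest each centroid.
#' @export
clusterPopulations <- function(projections, k = 3L, seed) {
  stopifnot(is.list(projections), length(projections) >= 1L, k >= 1L)
  pooled <- do.call(rbind, lapply(projections, slot, "coords"))
  labels <- vapply(projections, slot, character(1), "label")
  sizes <- vapply(projections, function(p) nrow(p@coords), integer(1))
  distinct <- nrow(unique(pooled))
  if (k > 1L && distinct == 1L)
    stop("all projected points are identical; cannot form ", k,
         " clusters")
  if (distinct < k)
    stop("fewer distinct points (", distinct, ") than clusters (", k, ")")
  if (k == 1L) {
    assign <- rep(1L, nrow(pooled))
    centers <- matrix(colMeans(pooled), 1, 2)
  } else {
    km <- withSeed(as.integer(seed),
      stats::kmeans(pooled, centers = k, nstart = 50L, iter.max = 100L))
    # stable labels: decreasing pooled cluster size, centroid as tie-break
    ord <- order(-tabulate(km$cluster, k), km$centers[, 1],
                 km$centers[, 2])
    relab <- match(seq_len(k), ord)
    assign <- relab[km$cluster]
    centers <- km$centers[ord, , drop = FALSE]
  }
  splits <- split(assign, rep(seq_along(projections), sizes))
  occ <- t(vapply(splits, function(a) tabulate(a, k) / length(a),
                  numeric(k)))
  dimnames(occ) <- list(labels, paste0("cluster", seq_len(k)))
  reps <- do.call(rbind, lapply(seq_len(k), function(cl) {
    d2 <- rowSums(sweep(pooled, 2L, centers[cl, ])^2)
    d2[assign != cl] <- Inf
    best <- which.min(d2)
    src <- findInterval(best - 1L, cumsum(sizes), left.open = FALSE) + 1L
    idx <- best - c(0L, cumsum(sizes))[src]
    data.frame(cluster = cl, label = labels[src], structureIndex = idx,
               pc1 = pooled[best, 1], pc2 = pooled[best, 2])
  }))
  new("ClusterSummary", k = as.integer(k), occupancy = occ,
      assignments = splits, representatives = reps,
      assignmentRule = sprintf(
        "k-means on pooled projections, k = %d, 50 restarts, seed %d",
        k, as.integer(seed)))
}

#' @rdname occupancy
#' @export
setMethod("occupancy", "ClusterSummary", function(x) x@occupancy)

setMethod("show", "ClusterSummary", function(object) {
  cat(sprintf("ClusterSummary (%s)\n", object@assignmentRule))
  print(round(100 * object@occupancy, 1))
})

#' Mean absolute accessibility change over a set of SNPs
#'
#' For several variants of one sequence, averages the per-nucleotide
#' absolute change in pairing probability |s_k(mutant) - s_k(WT)|.
#' Peaks localise the structural element that the variants collectively
#' perturb.
#'
#' @inheritParams partitionFunction
#' @param mutations non-empty list of [Mutation]s (or notation strings).
#' @return numeric vector of length n.
#' @export
meanAbsDeltaAccessibility <- function(seq, mutations,
                                      model = defaultEnergyModel()) {
  seq <- rnaSequence(seq)
  if (length(mutations) == 0L)
    stop("at least one mutation is required")
  mutations <- lapply(mutations, function(m)
    if (is.character(m)) parseMutation(m, seq) else .checkMutation(m, seq))
  wt <- accessibility(partitionFunction(seq, model))
  deltas <- vapply(mutations, function(m) {
    abs(accessibility(partitionFunction(applyMutation(seq, m), model)) -
        wt)
  }, numeric(length(seq)))
  rowMeans(matrix(deltas, nrow = length(seq)))
}

#' Partition-based versus MFE-based correlation distributions
#'
#' For every one of the 3n substitutions, two scores: (a) the Pearson
#' correlation of wild-type and mutant accessibility vectors (ensemble
#' view) and (b) the correlation of the binary paired/unpaired vectors
#' of the two MFE structures (single-structure view). The ensemble view
#' is far less sensitive to mutation, which is what makes its
#' correlation distribution usable for rank p-values.
#'
#' @inheritParams mutationScan
#' @return data.frame: mutation, position, wild, variant, partition
#'   (correlation a), mfe (correlation b).
#' @export
mfeVsPartitionDistributions <- function(seq, model = defaultEnergyModel(),
                                        budget = 1000L, force = FALSE) {
  seq <- rnaSequence(seq)
  n <- length(seq)
  if (n > budget && !force)
    stop("sequence length ", n, " exceeds the scan budget of ", budget,
         "; pass force = TRUE to scan anyway")
  wtAcc <- accessibility(partitionFunction(seq, model))
  wtBits <- structureVector(mfeStructure(seq, model)$structure)
  muts <- enumerateMutations(seq)
  part <- numeric(length(muts))
  mfe <- numeric(length(muts))
  for (k in seq_along(muts)) {
    mseq <- applyMutation(seq, muts[[k]])
    part[k] <- safeCorrelation(
      wtAcc, accessibility(partitionFunction(mseq, model)))
    mfe[k] <- safeCorrelation(
      wtBits, structureVector(mfeStructure(mseq, model)$structure))
  }
  data.frame(
    mutation = vapply(muts, as.character, character(1)),
    position = vapply(muts, slot, integer(1), "position"),
    wild = vapply(muts, slot, character(1), "wild"),
    variant = vapply(muts, slot, character(1), "variant"),
    partition = part, mfe = mfe, stringsAsFactors = FALSE)
}
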