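# helper: wrap hand-built pair matrices as an EnsembleSample
syntheticSample <- function(pairsList, n, label = "synthetic") {
  new("EnsembleSample", pairsList = pairsList, n = as.integer(n),
      seed = 0L, count = length(pairsList), label = label)
}

test_that("structure bit vectors encode paired residues", {
  expect_identical(structureVector(secondaryStructure(NULL, 5)),
                   integer(5))
  st <- secondaryStructure(rbind(c(1, 9), c(2, 8), c(3, 7)), 9)
  expect_identical(structureVector(st),
                   c(1L, 1L, 1L, 0L, 0L, 0L, 1L, 1L, 1L))
  expect_error(structureVector(rbind(c(1, 9)), n = 5), "exceeds")
  # vector sum = 2 x number of pairs for every sampled structure
  s <- sampleStructures("GGGAAACCC", count = 200, seed = 3)
  bits <- structureVectors(s)
  expect_identical(rowSums(bits),
                   2 * vapply(s@pairsList, nrow, integer(1)))
})

test_that("the shared basis finds the separating axis of two clouds", {
  # two clouds separated along bits (1,2); independent noise on (5,9)
  # kept rare so the separation eigenvalue clearly dominates
  mk <- function(group, k, seed) {
    noise <- withSeed(seed, stats::rbinom(k, 1, 0.15))
    lapply(seq_len(k), function(r) {
      p <- NULL
      if (group == 2) p <- rbind(p, c(1, 2))
      if (noise[r] == 1) p <- rbind(p, c(5, 9))
      if (is.null(p)) matrix(integer(0), 0, 2) else p
    })
  }
  s1 <- syntheticSample(mk(1, 500, 41), 12, "cloudA")
  s2 <- syntheticSample(mk(2, 500, 42), 12, "cloudB")
  basis <- buildSharedBasis(list(s1, s2), subsample = 500, seed = 43)
  sep <- c(1, 1, rep(0, 10)) / sqrt(2)
  cosine <- abs(sum(basis@rotation[, 1] * sep))
  expect_gt(cosine, 0.99)
  expect_gte(basis@explainedVar[1], basis@explainedVar[2])
  # deterministic sign convention
  expect_gt(basis@rotation[which.max(abs(basis@rotation[, 1])), 1], 0)
})

test_that("degenerate pooled subsamples are refused", {
  flat <- syntheticSample(replicate(50, matrix(integer(0), 0, 2),
                                    simplify = FALSE), 8)
  expect_warning(expect_error(
    buildSharedBasis(list(flat), subsample = 100, seed = 1),
    "degenerate"), "only 50 structures")
})

test_that("projection is centred, rigid and basis-faithful", {
  s1 <- sampleStructures("GGGGAAACCCC", count = 400, seed = 8)
  s2 <- sampleStructures("GGGGAAACCCU", count = 400, seed = 9)
  # subsample >= ensemble size: the basis uses every structure, so the
  # pooled projection must be exactly centred
  suppressWarnings(
    basis <- buildSharedBasis(list(s1, s2), subsample = 400, seed = 10))
  p1 <- projectSample(s1, basis)
  p2 <- projectSample(s2, basis)
  pooled <- rbind(p1@coords, p2@coords)
  expect_lt(max(abs(colMeans(pooled))), 1e-9)

  # identical structures map to identical coordinates
  bits <- structureVectors(s1)
  dup <- which(duplicated(bits) | duplicated(bits, fromLast = TRUE))
  if (length(dup) >= 2) {
    same <- which(apply(bits, 1, paste, collapse = "") ==
                  paste(bits[dup[1], ], collapse = ""))
    expect_equal(p1@coords[same[1], ], p1@coords[same[2], ])
  }

  # orthogonal projection contracts distances
  for (k in 1:20) {
    i <- sample(400, 1); j <- sample(400, 1)
    dproj <- sqrt(sum((p1@coords[i, ] - p1@coords[j, ])^2))
    dbits <- sqrt(sum((bits[i, ] - bits[j, ])^2))
    expect_lte(dproj, dbits + 1e-9)
  }

  expect_error(projectSample(sampleStructures("GAAAC", count = 10,
                                              seed = 1), basis),
               "does not match")
})

test_that("cluster occupancies are exact on constructed clouds", {
  coords <- rbind(
    matrix(rnorm(600, mean = 0, sd = 0.05), ncol = 2),
    matrix(rnorm(1400, mean = 10, sd = 0.05), ncol = 2))
  pr <- new("PcaProjection", label = "mix", coords = coords,
            provenance = list())
  cs <- clusterPopulations(list(pr), k = 2, seed = 5)
  expect_equal(sort(as.numeric(occupancy(cs))), c(0.3, 0.7))
  expect_equal(rowSums(occupancy(cs)), c(mix = 1))

  # k = 1: everything in one cluster
  cs1 <- clusterPopulations(list(pr), k = 1, seed = 5)
  expect_equal(as.numeric(occupancy(cs1)), 1)

  # degenerate: identical points cannot form 2 clusters
  flat <- new("PcaProjection", label = "flat",
              coords = matrix(0, 50, 2), provenance = list())
  expect_error(clusterPopulations(list(flat), k = 2, seed = 5),
               "identical")

  # representatives sit inside their own cluster
  expect_identical(nrow(cs@representatives), 2L)
  expect_true(all(cs@representatives$cluster %in% 1:2))
})

test_that("label order does not change occupancies", {
  d <- canonicalSwitch()
  wt <- d@sequence
  mut <- applyMutation(wt, d@toggling)
  s1 <- sampleStructures(wt, count = 800, seed = 21)
  s2 <- sampleStructures(mut, count = 800, seed = 22)
  run <- function(samples) {
    basis <- buildSharedBasis(samples, subsample = 400, seed = 23)
    pr <- lapply(samples, projectSample, basis = basis)
    occupancy(clusterPopulations(pr, k = 2, seed = 24))
  }
  o12 <- run(list(s1, s2))
  o21 <- run(list(s2, s1))
  expect_equal(o12[rownames(o21), ], o21, tolerance = 1e-9)
})

test_that("mean absolute accessibility change localises the perturbation", {
  s <- randomRnaSequence(20, seed = 55)
  muts <- enumerateMutations(s)[c(2, 10)]
  wt <- accessibility(partitionFunction(s))
  single <- meanAbsDeltaAccessibility(s, muts[1])
  direct <- abs(accessibility(partitionFunction(
    applyMutation(s, muts[[1]]))) - wt)
  expect_equal(single, direct, tolerance = 1e-12)
  both <- meanAbsDeltaAccessibility(s, muts)
  expect_length(both, 20L)
  expect_error(meanAbsDeltaAccessibility(s, list()), "at least one")

  # pair-free sequence stays pair-free under a tail mutation
  expect_equal(meanAbsDeltaAccessibility("AAAAAAAAAA", list("A2C")),
               rep(0, 10))

  # switch fixture: mutations breaking helix-A pairs concentrate the
  # signal inside the designed helices
  d <- canonicalSwitch()
  helixMuts <- lapply(1:3, function(k) {
    pos <- d@helixA[k, 1]
    wildb <- substr(residues(d@sequence), pos, pos)
    partner <- substr(residues(d@sequence), d@helixA[k, 2],
                      d@helixA[k, 2])
    mutation(pos, wildb, partner)
  })
  delta <- meanAbsDeltaAccessibility(d@sequence, helixMuts)
  helixPositions <- unique(as.vector(rbind(d@helixA, d@helixB)))
  expect_true(which.max(delta) %in% helixPositions)
})

test_that("partition-based correlations dominate MFE-based ones", {
  # a sequence so short that no single mutant can pair either: both
  # views stay flat, r = 1 throughout
  dist0 <- mfeVsPartitionDistributions("AAAA")
  expect_true(all(dist0$partition == 1))
  expect_true(all(dist0$mfe == 1))

  # several mutants here have an open-chain MFE, so the zero-variance
  # policy (r = 0 with a warning) fires by design
  dists <- suppressWarnings(mfeVsPartitionDistributions("GGGAAACCC"))
  expect_identical(nrow(dists), 27L)
  # MFE column against oracle argmin bit vectors (where unique)
  o <- hairpinOracle()
  wtArg <- which(abs(o$energies - min(o$energies)) < 1e-9)
  expect_length(wtArg, 1L)
  wtBits <- structureVector(o$structures[[wtArg]])
  for (k in seq_len(nrow(dists))) {
    mseq <- applyMutation("GGGAAACCC",
                          mutation(dists$position[k], dists$wild[k],
                                   dists$variant[k]))
    om <- oracleEnsemble(mseq)
    argmin <- which(abs(om$energies - min(om$energies)) < 1e-9)
    if (length(argmin) == 1L) {
      mbits <- structureVector(om$structures[[argmin]])
      expect_equal(dists$mfe[k],
                   suppressWarnings(safeCorrelation(wtBits, mbits)),
                   tolerance = 1e-9)
    }
  }
  # ensemble view is the less mutation-sensitive of the two
  s <- randomRnaSequence(40, seed = 66)
  dd <- mfeVsPartitionDistributions(s)
  expect_gte(median(dd$partition), median(dd$mfe))
})
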