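test_that("enumeration returns exactly the admissible nested structures", {
  # no pair possible among A residues: only the open chain
  e <- enumerateStructures("AAAA")
  expect_length(e, 1L)
  expect_identical(nrow(basePairs(e[[1]]$structure)), 0L)
  expect_equal(e[[1]]$energy, 0)

  # GAAAC: open chain plus the single G1:C5 pair (loop length 3)
  e <- enumerateStructures("GAAAC")
  expect_length(e, 2L)
  npairs <- vapply(e, function(x) nrow(basePairs(x$structure)), integer(1))
  expect_setequal(npairs, c(0L, 1L))

  # GGGAAACCC: count validated by an independent subset enumeration
  e <- enumerateStructures("GGGAAACCC")
  expect_length(e, countStructuresBySubsets("GGGAAACCC"))
  expect_identical(anyDuplicated(
    vapply(e, function(x) toDotBracket(x$structure), character(1))), 0L)

  expect_error(enumerateStructures(randomRnaSequence(25, seed = 1)),
               "cap of 20")
})

test_that("DP partition function equals exhaustive enumeration", {
  # the zero-energy two-state case: Z = 2, P(1,5) = 1/2
  z <- zeroEnergyModel()
  b <- partitionFunction("GAAAC", z)
  expect_equal(exp(logPartition(b)), 2)
  expect_equal(pairingProbabilities(b)[1, 5], 0.5)

  # oracle equivalence plus matrix invariants on seeded random sequences
  set.seed(101)
  for (k in 1:40) {
    s <- randomRnaSequence(sample(5:14, 1), gc = runif(1, 0.3, 0.7),
                           seed = 3000 + k)
    o <- oracleEnsemble(s)
    b <- partitionFunction(s)
    P <- pairingProbabilities(b)
    expect_lt(max(abs(P - o$probs)), 1e-9)
    expect_equal(exp(logPartition(b)), o$Z, tolerance = 1e-9)
    expect_identical(P, t(P))
    expect_true(all(P >= 0 & P <= 1))
    expect_true(all(rowSums(P) <= 1 + 1e-9))
  }
})

test_that("disallowed and too-close pairs have exactly zero probability", {
  m <- defaultEnergyModel()
  s <- randomRnaSequence(12, seed = 77)
  P <- pairingProbabilities(partitionFunction(s))
  res <- strsplit(residues(s), "")[[1]]
  for (i in 1:11) for (j in (i + 1):12) {
    disallowed <- !(paste0(res[i], res[j]) %in% m@allowedPairs) ||
      (j - i - 1 < m@minHairpin)
    if (disallowed) expect_identical(P[i, j], 0)
  }
})

test_that("MFE structure attains the enumerated minimum", {
  mf <- mfeStructure("AAAA")
  expect_identical(nrow(basePairs(mf$structure)), 0L)
  expect_equal(mf$energy, 0)

  for (k in 1:15) {
    s <- randomRnaSequence(sample(8:14, 1), seed = 4000 + k)
    o <- oracleEnsemble(s)
    mf <- mfeStructure(s)
    expect_equal(mf$energy, min(o$energies), tolerance = 1e-9)
    # the traced structure is a member of the argmin set
    keys <- vapply(o$structures, toDotBracket, character(1))
    argmin <- keys[abs(o$energies - min(o$energies)) < 1e-9]
    expect_true(toDotBracket(mf$structure) %in% argmin)
    # MFE single-structure weight dominates every enumerated structure
    expect_true(all(exp(-mf$energy / thermalEnergy(defaultEnergyModel()))
                    >= exp(-o$energies / thermalEnergy(defaultEnergyModel()))
                    - 1e-12))
  }
})

test_that("sampling is Boltzmann-consistent and seed-reproducible", {
  # a sequence with no possible pair yields only open chains
  s <- sampleStructures("AAAAAA", count = 100, seed = 5)
  expect_identical(length(s), 100L)
  expect_true(all(vapply(s@pairsList, nrow, integer(1)) == 0L))

  # two equal-weight states: frequency of the paired state near 1/2
  z <- zeroEnergyModel()
  s <- sampleStructures("GAAAC", z, count = 10000, seed = 6)
  paired <- mean(vapply(s@pairsList, nrow, integer(1)) == 1L)
  expect_lt(abs(paired - 0.5), 3 * sqrt(0.25 / 10000))

  # reproducibility: identical (sequence, model, count, seed)
  a <- sampleStructures("GGGAAACCC", count = 500, seed = 9)
  b <- sampleStructures("GGGAAACCC", count = 500, seed = 9)
  expect_identical(a@pairsList, b@pairsList)
  expect_identical(a@seed, 9L)
  # a different seed gives a different draw
  d <- sampleStructures("GGGAAACCC", count = 500, seed = 10)
  expect_false(identical(a@pairsList, d@pairsList))
})

test_that("sampled frequencies track exact Boltzmann probabilities", {
  o <- hairpinOracle()
  keys <- vapply(o$structures, toDotBracket, character(1))
  s <- sampleStructures("GGGAAACCC", count = 4000, seed = 11)
  got <- vapply(structures(s), toDotBracket, character(1))
  expect_true(all(got %in% keys))
  emp <- as.numeric(table(factor(got, levels = keys))) / 4000
  tv <- 0.5 * sum(abs(emp - o$probabilities))
  expect_lt(tv, 0.05)
})
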