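test_that("mutations apply at exactly one position with validation", {
  expect_identical(residues(applyMutation("GAAAC", "A2C")), "GCAAC")
  expect_error(applyMutation("GAAAC", "C2G"),
               "expected C, found A")
  expect_error(applyMutation("GAAAC", parseMutation("A2C", "GAAAC")),
               NA)
  expect_error(parseMutation("A9C", "GAAAC"), "out of range")
  expect_error(parseMutation("33G", "GAAAC"), "malformed")

  # a longer fixture: only the stated position changes
  s <- randomRnaSequence(50, seed = 20)
  pos33 <- substr(residues(s), 33, 33)
  var <- setdiff(c("A", "C", "G", "U"), pos33)[1]
  m <- mutation(33, pos33, var)
  ms <- applyMutation(s, m)
  diffpos <- which(strsplit(residues(s), "")[[1]] !=
                   strsplit(residues(ms), "")[[1]])
  expect_identical(diffpos, 33L)
})

test_that("all 3n substitutions are enumerated in canonical order", {
  m1 <- enumerateMutations("A")
  expect_length(m1, 3L)
  expect_identical(vapply(m1, as.character, character(1)),
                   c("A1C", "A1G", "A1U"))
  expect_length(enumerateMutations(randomRnaSequence(50, seed = 1)), 150L)
  expect_length(enumerateMutations(randomRnaSequence(533, seed = 1)),
                1599L)
})

test_that("accessibility is the column sums of the pairing matrix", {
  n <- 8L
  P <- matrix(0, n, n)
  P[2, 7] <- 0.8
  P[7, 2] <- 0.8
  b <- new("BasePairProbMatrix", probs = P, logZ = 1, seqId = "toy")
  expect_equal(accessibility(b), c(0, .8, 0, 0, 0, 0, .8, 0))
  zero <- new("BasePairProbMatrix", probs = matrix(0, 4, 4), logZ = 0,
              seqId = "z")
  expect_equal(accessibility(zero), rep(0, 4))
  # against the enumeration oracle
  o <- hairpinOracle()
  expect_equal(accessibility(partitionFunction("GGGAAACCC")),
               o$accessibility, tolerance = 1e-9)
})

test_that("degenerate Pearson cases follow the stated policy", {
  expect_identical(safeCorrelation(rep(0, 5), rep(0, 5)), 1)
  expect_warning(r <- safeCorrelation(rep(0, 5), rep(1, 5)),
                 "constant")
  expect_identical(r, 0)
  expect_warning(r2 <- safeCorrelation(rep(0.3, 5), c(0, 1, 0, 1, 1)),
                 "constant")
  expect_identical(r2, 0)
  # a mutation on a pair-free sequence keeps both vectors at zero
  expect_identical(structuralCorrelation("AAAAAAAAAA", "A5C"), 1)
})

test_that("a scan scores every mutation against the oracle", {
  scan <- mutationScan("GGGAAACCC")
  tab <- correlations(scan)
  expect_identical(nrow(tab), 27L)
  expect_true(all(tab$correlation <= 1 + 1e-12))

  o <- hairpinOracle()
  for (k in seq_len(nrow(tab))) {
    mseq <- applyMutation("GGGAAACCC",
                          mutation(tab$position[k], tab$wild[k],
                                   tab$variant[k]))
    om <- oracleEnsemble(mseq)
    expect_equal(tab$correlation[k],
                 safeCorrelation(o$accessibility, om$accessibility),
                 tolerance = 1e-9)
  }

  # heat map: wild-type cells are NA, scored cells match the table
  hm <- heatMap(scan)
  expect_identical(dim(hm), c(4L, 9L))
  expect_identical(sum(is.na(hm)), 9L)
  expect_equal(unname(hm["A", 1]),
               tab$correlation[tab$mutation == "G1A"])
})

test_that("scan values equal standalone recomputation", {
  s <- randomRnaSequence(15, seed = 30)
  tab <- correlations(mutationScan(s))
  pick <- c(1L, 17L, 45L)
  for (k in pick)
    expect_equal(structuralCorrelation(s, tab$mutation[k]),
                 tab$correlation[k], tolerance = 1e-12)
})

test_that("empirical p-values reproduce the worked rank arithmetic", {
  # synthetic scans with known distinct correlation values exercise the
  # ranking and the rank/3n arithmetic at the stated sizes
  syntheticScan <- function(n, seed) {
    s <- randomRnaSequence(n, seed = seed)
    muts <- enumerateMutations(s)
    r <- withSeed(seed + 1L, stats::runif(length(muts), -0.5, 1))
    riboSnitch:::.scanResult(s, muts, r, defaultEnergyModel(),
                             engine = "internal")
  }
  scan150 <- syntheticScan(50, 60)
  tab <- correlations(scan150)
  sixth <- tab$mutation[order(tab$correlation)][6]
  score <- empiricalPValue(sixth, scan150)
  expect_identical(score@rank, 6L)
  expect_identical(score@total, 150L)
  expect_equal(score@pValue, 0.04)

  scan1599 <- syntheticScan(533, 61)
  tab <- correlations(scan1599)
  t21 <- tab$mutation[order(tab$correlation)][21]
  score <- empiricalPValue(t21, scan1599)
  expect_identical(score@rank, 21L)
  expect_equal(score@pValue, 21 / 1599)
  expect_equal(round(score@pValue, 3), 0.013)

  # strict minimum in a tie-free scan: p = 1/(3n)
  lowest <- tab$mutation[which.min(tab$correlation)]
  expect_equal(empiricalPValue(lowest, scan1599)@pValue, 1 / 1599)

  expect_error(empiricalPValue("A9999C", scan150), "not among")
})

test_that("ranks are monotone in the correlation", {
  tab <- correlations(mutationScan(randomRnaSequence(15, seed = 31)))
  scan <- mutationScan(randomRnaSequence(15, seed = 31))
  p <- vapply(tab$mutation, function(m)
    empiricalPValue(m, scan)@pValue, numeric(1))
  ord <- order(tab$correlation)
  expect_true(all(diff(p[ord]) >= -1e-12))
  expect_true(all(p >= 1 / 45 & p <= 1))
})
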