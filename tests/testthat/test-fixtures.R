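test_that("random sequences are seeded, validated and composition-true", {
  expect_error(randomRnaSequence(0, seed = 1), ">= 1")
  expect_error(randomRnaSequence(10, gc = 1.2, seed = 1), "gc")
  a <- randomRnaSequence(50, seed = 7)
  b <- randomRnaSequence(50, seed = 7)
  expect_identical(residues(a), residues(b))
  expect_false(identical(residues(a),
                         residues(randomRnaSequence(50, seed = 8))))
  big <- randomRnaSequence(10000, gc = 0.5, seed = 9)
  gcObs <- mean(strsplit(residues(big), "")[[1]] %in% c("G", "C"))
  expect_true(gcObs >= 0.485 && gcObs <= 0.515)
})

test_that("designed hairpins fold into their stem", {
  expect_identical(residues(designHairpin(3, 3)), "GGGAAACCC")
  hp <- designHairpin(4, 5)
  expect_identical(length(hp), 2L * 4L + 5L)
  mf <- mfeStructure(hp)
  stem <- cbind(1:4, 13:10)
  expect_equal(basePairs(mf$structure),
               secondaryStructure(stem, 13)@pairs)
  # unique MFE confirmed by enumeration
  o <- oracleEnsemble(hp)
  expect_length(which(abs(o$energies - min(o$energies)) < 1e-9), 1L)
})

test_that("the switch design satisfies its certified invariants", {
  d <- canonicalSwitch()
  expect_s4_class(d, "SwitchDesign")
  expect_lte(length(d@sequence), 20L)
  # helices share residues, hence are mutually exclusive
  expect_gt(length(intersect(as.vector(d@helixA), as.vector(d@helixB))),
            0L)
  expect_gt(d@pHelixA, 0.8)
  # the toggling mutation disrupts a helix-A pair
  expect_true(d@toggling@position %in% as.vector(d@helixA))
  # scan rank of the toggling mutation in the lowest tenth
  sc <- empiricalPValue(d@toggling, mutationScan(d@sequence))
  expect_lte(sc@rank, 0.1 * sc@total)
  # neutral tail mutation leaves the ensemble intact
  expect_gt(structuralCorrelation(d@sequence, d@neutral), 0.99)
  # pure function of the seed
  expect_identical(residues(designSwitch(1)@sequence),
                   residues(d@sequence))
})
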