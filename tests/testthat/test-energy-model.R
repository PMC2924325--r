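test_that("the bundled parameter set parses with its invariants", {
  m <- defaultEnergyModel()
  expect_s4_class(m, "EnergyModel")
  expect_setequal(m@allowedPairs, c("AU", "UA", "GC", "CG", "GU", "UG"))
  expect_gte(m@minHairpin, 3L)
  expect_true(all(is.finite(m@stack)))
  expect_match(m@digest, "^[0-9a-f]{32}$")
  # strand-reversal symmetry of stacking: E(XY on WZ) = E(ZW on YX)
  rev2 <- function(p) paste0(substr(p, 2, 2), substr(p, 1, 1))
  for (o in m@allowedPairs) for (i in m@allowedPairs)
    expect_equal(m@stack[o, i], m@stack[rev2(i), rev2(o)])
})

test_that("malformed parameter files are rejected", {
  path <- system.file("extdata", "energy_params.txt",
                      package = "riboSnitch")
  lines <- readLines(path)
  bad <- tempfile(fileext = ".txt")

  writeLines(c(lines, "temperature 300"), bad)  # duplicate key
  expect_error(readEnergyParams(bad), "exactly once")

  # AU/CG mirrors to GC/UA, so perturbing one side breaks the symmetry
  asym <- sub("^stack AU CG -2.2$", "stack AU CG -9.9", lines)
  writeLines(asym, bad)
  expect_error(readEnergyParams(bad), "symmetry")
})

test_that("loop penalties extrapolate logarithmically beyond the table", {
  m <- defaultEnergyModel()
  lmax <- max(as.integer(names(m@hairpin)))
  expect_identical(loopEnergy(m, "hairpin", 3L), unname(m@hairpin["3"]))
  expected <- m@hairpin[as.character(lmax)] +
    m@extrapolationCoeff * thermalEnergy(m) * log(25 / lmax)
  expect_equal(loopEnergy(m, "hairpin", 25L), unname(expected))
  # monotone beyond the table
  long <- loopEnergy(m, "internal", c(15L, 20L, 30L))
  expect_true(all(diff(long) > 0))
  expect_error(loopEnergy(m, "bulge", 0L), "tabulated minimum")
})

test_that("parameter digest is stable and content-sensitive", {
  path <- system.file("extdata", "energy_params.txt",
                      package = "riboSnitch")
  m1 <- readEnergyParams(path)
  m2 <- readEnergyParams(path)
  expect_identical(m1@digest, m2@digest)
  tweaked <- sub("^hairpin 3 5.4$", "hairpin 3 5.5", readLines(path))
  tmp <- tempfile(fileext = ".txt")
  writeLines(tweaked, tmp)
  expect_false(readEnergyParams(tmp)@digest == m1@digest)
})
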