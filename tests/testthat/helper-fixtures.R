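# Shared fixtures and independent mini-oracles for the suite.

# Independent structure counter: enumerate all subsets of candidate
# pairs and keep the mutually compatible (non-crossing, disjoint) ones.
# A different algorithm from enumerateStructures(), used to validate it.
countStructuresBySubsets <- function(seq, model = defaultEnergyModel()) {
  seq <- rnaSequence(seq)
  res <- strsplit(residues(seq), "")[[1]]
  n <- length(res)
  h <- model@minHairpin
  cand <- list()
  for (i in seq_len(n)) for (j in seq_len(n))
    if (j - i - 1 >= h &&
        paste0(res[i], res[j]) %in% model@allowedPairs)
      cand[[length(cand) + 1]] <- c(i, j)
  m <- length(cand)
  stopifnot(m <= 20)  # 2^m subsets
  compatible <- function(a, b) {
    if (length(intersect(a, b)) > 0) return(FALSE)
    lo <- if (a[1] < b[1]) a else b
    hi <- if (a[1] < b[1]) b else a
    hi[2] < lo[2] || hi[1] > lo[2]  # nested or disjoint
  }
  count <- 0L
  for (mask in 0:(2^m - 1)) {
    sel <- which(bitwAnd(mask, 2^(seq_len(m) - 1)) > 0)
    ok <- TRUE
    if (length(sel) > 1)
      for (a in seq_along(sel)[-1]) for (b in seq_len(a - 1))
        if (!compatible(cand[[sel[a]]], cand[[sel[b]]])) {
          ok <- FALSE
          break
        }
    if (ok) count <- count + 1L
  }
  count
}

# Model with every energy term set to zero: all admissible structures
# get equal Boltzmann weight, so Z counts structures.
zeroEnergyModel <- function() {
  m <- defaultEnergyModel()
  m@stack[] <- 0
  m@hairpin[] <- 0
  m@bulge[] <- 0
  m@internal[] <- 0
  m@multiloopOffset <- 0
  m@multiloopBranch <- 0
  m@multiloopUnpaired <- 0
  m@extrapolationCoeff <- 0
  m
}

# lazily built, shared across test files
.fixtureCache <- new.env(parent = emptyenv())

canonicalSwitch <- function() {
  if (is.null(.fixtureCache$switch))
    .fixtureCache$switch <- designSwitch(1)
  .fixtureCache$switch
}

hairpinOracle <- function() {
  if (is.null(.fixtureCache$hp9))
    .fixtureCache$hp9 <- oracleEnsemble("GGGAAACCC")
  .fixtureCache$hp9
}
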