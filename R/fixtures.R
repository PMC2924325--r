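#' @include AllClasses.R oracle.R thermo.R snpfold.R
NULL

#' Seeded random RNA sequence
#'
#' Residues drawn i.i.d. with P(G) = P(C) = gc/2 and
#' P(A) = P(U) = (1-gc)/2. A pure function of its seed.
#'
#' @param n sequence length (>= 1).
#' @param gc target GC fraction in [0, 1].
#' @param seed integer seed.
#' @param id sequence identifier.
#' @return an [RnaSequence].
#' @export
randomRnaSequence <- function(n, gc = 0.5, seed,
                              id = sprintf("random_n%d_s%d", n, seed)) {
  n <- as.integer(n)
  if (n < 1L) stop("n must be >= 1")
  if (gc < 0 || gc > 1) stop("gc must lie in [0, 1]")
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, U = (1 - gc) / 2)
  res <- withSeed(seed,
    sample(RNA_BASES, n, replace = TRUE, prob = p[RNA_BASES]))
  rnaSequence(paste(res, collapse = ""), id = id)
}

#' Designed GC-stem hairpin
#'
#' `stem` G residues, an A loop, `stem` C residues - a construct whose
#' unique minimum free energy structure is the full stem at small
#' sizes.
#'
#' @param stem stem length in pairs.
#' @param loop loop length (>= minimum hairpin loop).
#' @return an [RnaSequence], e.g. "GGGAAACCC" for stem 3, loop 3.
#' @export
designHairpin <- function(stem, loop) {
  stopifnot(stem >= 1L, loop >= 3L)
  rnaSequence(paste0(strrep("G", stem), strrep("A", loop),
                     strrep("C", stem)),
              id = sprintf("hairpin_s%d_l%d", stem, loop))
}

#' Design a two-state switch construct
#'
#' Rejection-samples short (<= 20 nt) sequences of the form
#' S1-loop-S2-loop-S3-tail in which helix A (S1:S2) and helix B (S2:S3)
#' are mutually exclusive because they share S2. Candidates are
#' certified against the enumeration oracle and the scoring engine
#' before acceptance: the wild type must hold helix A fully formed with
#' ensemble probability > 0.8; the designated toggling mutation (which
#' disrupts a helix-A pair) must rank in the lowest tenth of the full
#' 3n scan; and the designated neutral tail mutation must score
#' r > 0.99. The design is a pure function of its seed.
#'
#' @param seed integer seed.
#' @param model an [EnergyModel].
#' @param maxAttempts give up after this many candidates.
#' @return a [SwitchDesign].
#' @export
designSwitch <- function(seed, model = defaultEnergyModel(),
                         maxAttempts = 1e5L) {
  arm <- 4L; loop1 <- 3L; loop2 <- 3L; tail <- 2L
  comp <- c(A = "U", C = "G", G = "C", U = "A")
  for (attempt in seq_len(maxAttempts)) {
    s1 <- withSeed(seed + attempt - 1L,
      sample(c("G", "C"), arm, replace = TRUE))
    s2 <- rev(unname(comp[s1]))
    # helix B: S2:S3, same pairing pattern but one terminal pair
    # weakened (G:C -> G:U or A:U -> A:A mismatch) so A dominates WT
    s3 <- rev(unname(comp[s2]))
    s3[arm] <- if (s3[arm] == "C") "U" else "A"
    seqtxt <- paste(c(s1, rep("A", loop1), s2, rep("A", loop2), s3,
                      rep("A", tail)), collapse = "")
    seq <- rnaSequence(seqtxt, id = sprintf("switch_s%d", seed))
    n <- nchar(seqtxt)
    off2 <- arm + loop1          # S2 starts at off2 + 1
    off3 <- off2 + arm + loop2   # S3 starts at off3 + 1
    helixA <- cbind(seq_len(arm), off2 + arm + 1L - seq_len(arm))
    helixB <- cbind(off2 + seq_len(arm), off3 + arm + 1L - seq_len(arm))

    oracle <- oracleEnsemble(seq, model, cap = n)
    pA <- .pHelixFormed(oracle, helixA)
    if (pA <= 0.8) next

    # toggling mutation: break a central helix-A pair by mutating the
    # S1 side to its partner's identity
    pos <- 2L
    wild <- substr(seqtxt, pos, pos)
    partner <- substr(seqtxt, helixA[pos, 2], helixA[pos, 2])
    if (wild == partner) next
    toggling <- mutation(pos, wild, partner)

    scan <- mutationScan(seq, model)
    score <- empiricalPValue(toggling, scan)
    if (score@rank > 0.1 * score@total) next

    # neutral mutation: best-correlating substitution of the last tail
    # base
    tailPos <- n
    tailWild <- substr(seqtxt, tailPos, tailPos)
    tab <- correlations(scan)
    cand <- tab[tab$position == tailPos, , drop = FALSE]
    best <- cand[which.max(cand$correlation), ]
    if (best$correlation <= 0.99) next
    neutral <- mutation(tailPos, tailWild, best$variant)

    return(new("SwitchDesign", sequence = seq, helixA = helixA,
               helixB = helixB, toggling = toggling, neutral = neutral,
               pHelixA = pA))
  }
  stop("no admissible switch design found in ", maxAttempts,
       " attempts")
}

# ensemble probability that every pair of `helix` is formed
.pHelixFormed <- function(oracle, helix) {
  key <- paste(helix[, 1], helix[, 2], sep = "-")
  hit <- vapply(oracle$structures, function(st) {
    p <- basePairs(st)
    all(key %in% paste(p[, 1], p[, 2], sep = "-"))
  }, logical(1))
  sum(oracle$probabilities[hit])
}

setMethod("show", "SwitchDesign", function(object) {
  cat(sprintf(paste0(
    "SwitchDesign '%s' (%d nt)\n  %s\n",
    "  helix A pairs %s (P formed = %.3f); helix B pairs %s\n",
    "  toggling %s, neutral %s\n"),
    seqId(object@sequence), length(object@sequence),
    residues(object@sequence),
    paste(sprintf("%d:%d", object@helixA[, 1], object@helixA[, 2]),
          collapse = " "),
    object@pHelixA,
    paste(sprintf("%d:%d", object@helixB[, 1], object@helixB[, 2]),
          collapse = " "),
    as.character(object@toggling), as.character(object@neutral)))
})
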