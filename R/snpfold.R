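#' @include AllClasses.R AllGenerics.R thermo.R
NULL

#' Construct a mutation
#'
#' @param position 1-based position.
#' @param wild,variant residues (T accepted, normalised to U).
#' @return a [Mutation].
#' @export
mutation <- function(position, wild, variant) {
  norm <- function(b) chartr("t", "u", chartr("T", "U", toupper(b)))
  new("Mutation", position = as.integer(position),
      wild = norm(wild), variant = norm(variant))
}

#' @describeIn mutation compact notation, e.g. "C33G".
#' @param x a [Mutation].
#' @export
setMethod("as.character", "Mutation", function(x)
  paste0(x@wild, x@position, x@variant))

setMethod("show", "Mutation", function(object)
  cat("Mutation", as.character(object), "\n"))

#' Parse compact mutation notation
#'
#' Accepts `<wild base><1-based position><variant base>`, e.g. "C33G";
#' T is accepted and normalised to U. The wild base must match the
#' sequence residue at that position.
#'
#' @param text mutation string.
#' @param seq the target [RnaSequence] (or coercible); used to validate
#'   position and wild base.
#' @return a validated [Mutation].
#' @export
parseMutation <- function(text, seq) {
  stopifnot(is.character(text), length(text) == 1L)
  m <- regmatches(text,
       regexec("^([ACGUTacgut])([0-9]+)([ACGUTacgut])$", text))[[1]]
  if (length(m) != 4L)
    stop("malformed mutation '", text,
         "': expected <base><position><base>, e.g. C33G")
  mut <- mutation(as.integer(m[3]), m[2], m[4])
  .checkMutation(mut, rnaSequence(seq))
  mut
}

.checkMutation <- function(mut, seq) {
  n <- length(seq)
  if (mut@position > n)
    stop("position ", mut@position, " out of range for '", seqId(seq),
         "' (length ", n, ")")
  found <- substr(residues(seq), mut@position, mut@position)
  if (found != mut@wild)
    stop("wild-base mismatch at position ", mut@position, ": expected ",
         mut@wild, ", found ", found)
  invisible(mut)
}

#' Apply a single-nucleotide substitution
#'
#' @param seq an [RnaSequence] (or coercible).
#' @param mut a [Mutation] or compact notation string.
#' @return a new [RnaSequence] differing from `seq` at exactly the
#'   mutated position; its id is suffixed with the mutation.
#' @examples
#' residues(applyMutation("GAAAC", "A2C"))  # "GCAAC"
#' @export
applyMutation <- function(seq, mut) {
  seq <- rnaSequence(seq)
  if (is.character(mut)) mut <- parseMutation(mut, seq)
  .checkMutation(mut, seq)
  res <- residues(seq)
  substr(res, mut@position, mut@position) <- mut@variant
  rnaSequence(res, id = paste0(seqId(seq), "_", as.character(mut)))
}

#' Enumerate all 3n single-nucleotide substitutions
#'
#' Every position times every non-wild base, in deterministic order:
#' position ascending, variant base A < C < G < U.
#'
#' @param seq an [RnaSequence] (or coercible).
#' @return list of exactly 3n [Mutation]s.
#' @export
enumerateMutations <- function(seq) {
  seq <- rnaSequence(seq)
  res <- .resVector(seq)
  out <- vector("list", 3L * length(seq))
  k <- 0L
  for (pos in seq_along(res))
    for (b in RNA_BASES)
      if (b != res[pos]) {
        k <- k + 1L
        out[[k]] <- mutation(pos, res[pos], b)
      }
  out
}

#' Pearson correlation with degenerate-case policy
#'
#' Zero-variance vectors make the Pearson coefficient undefined; to keep
#' every mutation rankable the policy is: both vectors constant and
#' element-wise equal (tolerance 1e-12) gives r = 1; constant but
#' unequal, or exactly one constant, gives r = 0 with a warning.
#'
#' @param x,y numeric vectors of equal length.
#' @return correlation in [-1, 1].
#' @export
safeCorrelation <- function(x, y) {
  stopifnot(length(x) == length(y))
  cx <- diff(range(x)) <= 1e-12
  cy <- diff(range(y)) <= 1e-12
  if (cx && cy) {
    if (max(abs(x - y)) <= 1e-12) return(1)
    warning("both vectors constant but unequal; correlation set to 0")
    return(0)
  }
  if (cx || cy) {
    warning("one vector constant; correlation set to 0")
    return(0)
  }
  stats::cor(x, y)
}

#' Structural correlation of a mutation
#'
#' The riboSNitch score of a variant: the Pearson correlation between
#' the wild-type and mutant accessibility vectors (per-nucleotide
#' pairing probabilities, the column sums of the two base-pair
#' probability matrices). Values near 1 mean the ensemble is unchanged;
#' low values flag a global rearrangement.
#'
#' @inheritParams partitionFunction
#' @param mut a [Mutation] or compact notation string.
#' @param wtAccessibility optional precomputed wild-type accessibility
#'   vector (reused across a scan).
#' @return correlation in [-1, 1].
#' @export
structuralCorrelation <- function(seq, mut, model = defaultEnergyModel(),
                                  wtAccessibility = NULL,
                                  engine = c("internal", "external")) {
  engine <- match.arg(engine)
  seq <- rnaSequence(seq)
  if (is.character(mut)) mut <- parseMutation(mut, seq)
  if (is.null(wtAccessibility))
    wtAccessibility <-
      accessibility(partitionFunction(seq, model, engine))
  mutAcc <- accessibility(
    partitionFunction(applyMutation(seq, mut), model, engine))
  safeCorrelation(wtAccessibility, mutAcc)
}

#' Exhaustive single-mutation scan
#'
#' Computes the structural correlation for all 3n substitutions of a
#' sequence. The wild-type partition function is computed once and
#' reused. The result carries both a long table and the 4 x n heat-map
#' layout (rows A, C, G, U; wild-type cells are NA).
#'
#' @inheritParams partitionFunction
#' @param budget refuse sequences longer than this without
#'   `force = TRUE` (a 3n scan is O(n^4) overall).
#' @param force override the budget refusal.
#' @return a [MutationScanResult].
#' @export
mutationScan <- function(seq, model = defaultEnergyModel(),
                         budget = 1000L, force = FALSE,
                         engine = c("internal", "external")) {
  engine <- match.arg(engine)
  seq <- rnaSequence(seq)
  n <- length(seq)
  if (n > budget && !force)
    stop("sequence length ", n, " exceeds the scan budget of ", budget,
         "; pass force = TRUE to scan anyway")
  wt <- accessibility(partitionFunction(seq, model, engine))
  muts <- enumerateMutations(seq)
  r <- vapply(muts, function(m)
    structuralCorrelation(seq, m, model, wtAccessibility = wt,
                          engine = engine),
    numeric(1))
  .scanResult(seq, muts, r, model, engine = engine)
}

.scanResult <- function(seq, muts, r, model, engine) {
  n <- length(seq)
  res <- .resVector(seq)
  tab <- data.frame(
    mutation = vapply(muts, as.character, character(1)),
    position = vapply(muts, slot, integer(1), "position"),
    wild = vapply(muts, slot, character(1), "wild"),
    variant = vapply(muts, slot, character(1), "variant"),
    correlation = r, stringsAsFactors = FALSE)
  hm <- matrix(NA_real_, 4L, n, dimnames = list(RNA_BASES, NULL))
  hm[cbind(match(tab$variant, RNA_BASES), tab$position)] <-
    tab$correlation
  new("MutationScanResult", seqId = seqId(seq), n = as.integer(n),
      table = tab, heatmap = hm, engine = engine,
      paramDigest = model@digest)
}

#' @rdname correlations
#' @export
setMethod("correlations", "MutationScanResult", function(x) x@table)

#' @rdname seqId
#' @export
setMethod("seqId", "MutationScanResult", function(x) x@seqId)

#' Heat-map layout of a scan
#'
#' @param x a [MutationScanResult].
#' @return 4 x n matrix (rows A, C, G, U); NA marks wild-type cells.
#' @export
heatMap <- function(x) {
  stopifnot(is(x, "MutationScanResult"))
  x@heatmap
}

setMethod("show", "MutationScanResult", function(object) {
  cat(sprintf(paste0(
    "MutationScanResult '%s': %d mutations over %d nt (engine %s)\n",
    "  correlation range [%.4f, %.4f], median %.4f\n"),
    object@seqId, nrow(object@table), object@n, object@engine,
    min(object@table$correlation), max(object@table$correlation),
    stats::median(object@table$correlation)))
})

#' Rank-based empirical p-value of a scanned mutation
#'
#' The significance of a variant's structural correlation relative to
#' all possible mutations of the same sequence: rank = number of
#' scanned mutations with r <= r(target) (ties counted, self included),
#' p = rank / 3n. This normalises the correlation for sequence length
#' and composition.
#'
#' @param target a [Mutation] or compact notation string; must be one
#'   of the scanned mutations.
#' @param scan a [MutationScanResult].
#' @return a [SnpScore].
#' @export
empiricalPValue <- function(target, scan) {
  stopifnot(is(scan, "MutationScanResult"))
  key <- if (is.character(target)) target else as.character(target)
  tab <- scan@table
  hit <- which(tab$mutation == key)
  if (length(hit) != 1L)
    stop("mutation '", key, "' is not among the scanned mutations")
  r <- tab$correlation[hit]
  rank <- sum(tab$correlation <= r)
  total <- nrow(tab)
  new("SnpScore",
      mutation = mutation(tab$position[hit], tab$wild[hit],
                          tab$variant[hit]),
      correlation = r, rank = as.integer(rank),
      pValue = rank / total, total = as.integer(total))
}

setMethod("show", "SnpScore", function(object) {
  cat(sprintf(
    "SnpScore %s: r = %.4f, rank %d of %d, p = %.4g\n",
    as.character(object@mutation), object@correlation, object@rank,
    object@total, object@pValue))
})

#' Score one SNP end to end
#'
#' Convenience wrapper: runs the full 3n scan of the sequence and
#' returns the [SnpScore] of the variant of interest (which is itself a
#' member of the scanned set).
#'
#' @inheritParams mutationScan
#' @param snp a [Mutation] or compact notation string.
#' @return list with elements `score` (a [SnpScore]) and `scan` (the
#'   full [MutationScanResult]).
#' @export
scoreSnp <- function(seq, snp, model = defaultEnergyModel(),
                     budget = 1000L, force = FALSE,
                     engine = c("internal", "external")) {
  seq <- rnaSequence(seq)
  if (is.character(snp)) snp <- parseMutation(snp, seq)
  .checkMutation(snp, seq)
  scan <- mutationScan(seq, model, budget = budget, force = force,
                       engine = engine)
  list(score = empiricalPValue(snp, scan), scan = scan)
}
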