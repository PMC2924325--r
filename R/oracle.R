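#' @include AllClasses.R structure.R energy-model.R
NULL

#' Exhaustively enumerate all nested secondary structures
#'
#' Generates every distinct nested structure a sequence can form under
#' the model constraints (allowed pairs, minimum hairpin loop, interior
#' loop cap), including the open chain, each with its loop-decomposition
#' energy. This brute-force recursion is independent of the
#' dynamic-programming engine and serves as its validation oracle; the
#' structure count grows exponentially, so sequences longer than `cap`
#' are refused.
#'
#' @param seq an [RnaSequence] (or coercible).
#' @param model an [EnergyModel].
#' @param cap refuse sequences longer than this (default 20).
#' @return list with one element per structure, each a list with
#'   elements `structure` (a [SecondaryStructure]) and `energy`.
#' @examples
#' enumerateStructures("GAAAC")  # open chain and the single G:C pair
#' @export
enumerateStructures <- function(seq, model = defaultEnergyModel(),
                                cap = 20L) {
  seq <- rnaSequence(seq)
  n <- length(seq)
  if (n > cap)
    stop("sequence length ", n, " exceeds the enumeration cap of ", cap,
         " (combinatorial explosion); raise `cap` deliberately if needed")
  res <- .resVector(seq)
  h <- model@minHairpin
  canPair <- outer(seq_len(n), seq_len(n), function(i, j)
    j - i - 1L >= h) &
    outer(res, res, function(a, b) paste0(a, b) %in% model@allowedPairs)

  memo <- new.env(parent = emptyenv())
  # all pair sets on [i, j] as list of two-column matrices
  gen <- function(i, j) {
    if (j - i < h + 1L) return(list(matrix(integer(0), 0, 2)))
    key <- paste0(i, ":", j)
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    out <- gen(i + 1L, j)                      # i unpaired
    for (k in seq(i + h + 1L, j)) {
      if (!canPair[i, k]) next
      left <- gen(i + 1L, k - 1L)
      right <- if (k + 1L <= j) gen(k + 1L, j)
               else list(matrix(integer(0), 0, 2))
      for (L in left) for (R in right)
        out <- c(out, list(rbind(c(i, k), L, R)))
    }
    memo[[key]] <- out
    out
  }
  sets <- gen(1L, n)
  out <- vector("list", length(sets))
  keep <- logical(length(sets))
  for (s in seq_along(sets)) {
    st <- secondaryStructure(sets[[s]], n)
    e <- structureEnergy(st, seq, model)
    keep[s] <- is.finite(e)
    out[[s]] <- list(structure = st, energy = e)
  }
  out[keep]
}

#' Exact Boltzmann ensemble by enumeration
#'
#' Convenience wrapper around [enumerateStructures()]: the exact
#' partition value, per-structure Boltzmann probabilities, the exact
#' base-pair probability matrix and the exact accessibility vector,
#' all computed by brute force for validation of the DP engine.
#'
#' @inheritParams enumerateStructures
#' @return list with elements `structures` (list of
#'   [SecondaryStructure]), `energies`, `probabilities` (per structure),
#'   `Z`, `probs` (n x n matrix) and `accessibility`.
#' @export
oracleEnsemble <- function(seq, model = defaultEnergyModel(), cap = 20L) {
  seq <- rnaSequence(seq)
  n <- length(seq)
  enum <- enumerateStructures(seq, model, cap)
  energies <- vapply(enum, `[[`, numeric(1), "energy")
  w <- exp(-energies / thermalEnergy(model))
  Z <- sum(w)
  p <- w / Z
  P <- matrix(0, n, n)
  for (s in seq_along(enum)) {
    pr <- basePairs(enum[[s]]$structure)
    if (nrow(pr) > 0L)
      for (r in seq_len(nrow(pr))) {
        P[pr[r, 1], pr[r, 2]] <- P[pr[r, 1], pr[r, 2]] + p[s]
        P[pr[r, 2], pr[r, 1]] <- P[pr[r, 2], pr[r, 1]] + p[s]
      }
  }
  list(structures = lapply(enum, `[[`, "structure"),
       energies = energies, probabilities = p, Z = Z, probs = P,
       accessibility = colSums(P))
}
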