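#' @include AllClasses.R AllGenerics.R
NULL

#' Construct a secondary structure
#'
#' @param pairs two-column matrix of 1-based base pairs (i < j), or an
#'   empty matrix / NULL for the open chain.
#' @param n sequence length.
#' @return a [SecondaryStructure].
#' @export
secondaryStructure <- function(pairs = NULL, n) {
  if (is.null(pairs) || length(pairs) == 0L)
    pairs <- matrix(integer(0), 0, 2)
  pairs <- matrix(as.integer(pairs), ncol = 2)
  if (nrow(pairs) > 0L) pairs <- pairs[order(pairs[, 1]), , drop = FALSE]
  new("SecondaryStructure", pairs = pairs, n = as.integer(n))
}

#' @rdname basePairs
#' @export
setMethod("basePairs", "SecondaryStructure", function(x) x@pairs)

#' @describeIn secondaryStructure sequence length of the structure.
#' @export
setMethod("length", "SecondaryStructure", function(x) x@n)

setMethod("show", "SecondaryStructure", function(object) {
  cat(sprintf("SecondaryStructure (%d nt, %d pairs)\n  %s\n",
              object@n, nrow(object@pairs), toDotBracket(object)))
})

#' @rdname toDotBracket
#' @export
setMethod("toDotBracket", "SecondaryStructure", function(x) {
  chars <- rep(".", x@n)
  chars[x@pairs[, 1]] <- "("
  chars[x@pairs[, 2]] <- ")"
  paste(chars, collapse = "")
})

#' Parse dot-bracket notation
#'
#' @param text character scalar of '.', '(' and ')'.
#' @return a [SecondaryStructure].
#' @export
parseDotBracket <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  ch <- strsplit(text, "", fixed = TRUE)[[1]]
  if (!all(ch %in% c(".", "(", ")")))
    stop("dot-bracket text may only contain '.', '(' and ')'")
  open <- integer(0)
  pairs <- matrix(integer(0), 0, 2)
  for (k in seq_along(ch)) {
    if (ch[k] == "(") open <- c(open, k)
    else if (ch[k] == ")") {
      if (length(open) == 0L) stop("unbalanced ')' at position ", k)
      pairs <- rbind(pairs, c(open[length(open)], k))
      open <- open[-length(open)]
    }
  }
  if (length(open) > 0L) stop("unbalanced '(' at position ", open[1])
  secondaryStructure(pairs, length(ch))
}

#' Binary paired/unpaired encoding of a structure
#'
#' Element k is 1 if residue k is paired, else 0 - the parameterisation
#' used for principal-component analysis of sampled ensembles.
#'
#' @param s a [SecondaryStructure] or a two-column pair matrix.
#' @param n sequence length.
#' @return integer vector of 0/1 of length n.
#' @export
structureVector <- function(s, n = NULL) {
  if (is(s, "SecondaryStructure")) {
    if (is.null(n)) n <- s@n
    p <- s@pairs
  } else p <- s
  if (length(p) > 0L && max(p) > n) stop("pair index exceeds n")
  bits <- integer(n)
  bits[as.vector(p)] <- 1L
  bits
}

# direct children of each loop: returns list with one element per pair
# (in input row order) plus $root, each an integer vector of child rows
.loopChildren <- function(pairs, n) {
  m <- nrow(pairs)
  parent <- integer(m)  # 0 = exterior
  if (m > 1L) {
    o <- order(pairs[, 1])
    stack <- integer(0)
    for (r in o) {
      while (length(stack) > 0L &&
             pairs[stack[length(stack)], 2] < pairs[r, 1])
        stack <- stack[-length(stack)]
      parent[r] <- if (length(stack) > 0L) stack[length(stack)] else 0L
      stack <- c(stack, r)
    }
  }
  kids <- split(seq_len(m), factor(parent, levels = 0:m))
  names(kids) <- c("root", as.character(seq_len(m)))
  kids
}

#' Energy of a structure by loop decomposition
#'
#' Decomposes a nested structure into hairpin, stacked-pair, bulge,
#' interior and multibranch loops and sums their model energies. This is
#' an independent code path from the dynamic-programming engine and is
#' used, together with [enumerateStructures()], as its validation oracle.
#' Structures containing a bulge or interior loop larger than the model
#' cap are inadmissible and get energy `Inf`.
#'
#' @param structure a [SecondaryStructure].
#' @param seq an [RnaSequence] (or coercible).
#' @param model an [EnergyModel].
#' @return energy in kcal/mol (0 for the open chain, Inf if inadmissible).
#' @export
structureEnergy <- function(structure, seq, model = defaultEnergyModel()) {
  seq <- rnaSequence(seq)
  res <- .resVector(seq)
  pairs <- basePairs(structure)
  m <- nrow(pairs)
  if (m == 0L) return(0)
  for (r in seq_len(m))
    if (!.pairAllowed(model, res[pairs[r, 1]], res[pairs[r, 2]]))
      stop("pair ", pairs[r, 1], "-", pairs[r, 2], " is not an allowed pair")
  if (any(pairs[, 2] - pairs[, 1] - 1L < model@minHairpin))
    stop("a pair violates the minimum hairpin loop constraint")
  kids <- .loopChildren(pairs, length(seq))
  e <- 0
  for (r in seq_len(m)) {
    i <- pairs[r, 1]; j <- pairs[r, 2]
    ch <- kids[[as.character(r)]]
    if (length(ch) == 0L) {
      e <- e + loopEnergy(model, "hairpin", j - i - 1L)
    } else if (length(ch) == 1L) {
      k <- pairs[ch, 1]; l <- pairs[ch, 2]
      l1 <- k - i - 1L; l2 <- j - l - 1L
      if (l1 == 0L && l2 == 0L) {
        e <- e + model@stack[paste0(res[i], res[j]),
                             paste0(res[k], res[l])]
      } else if (l1 + l2 > model@maxInteriorUnpaired) {
        return(Inf)
      } else if (l1 == 0L || l2 == 0L) {
        e <- e + loopEnergy(model, "bulge", l1 + l2)
      } else {
        e <- e + loopEnergy(model, "internal", l1 + l2)
      }
    } else {
      unpaired <- (j - i - 1L) -
        sum(pairs[ch, 2] - pairs[ch, 1] + 1L)
      e <- e + model@multiloopOffset +
        model@multiloopBranch * (length(ch) + 1L) +
        model@multiloopUnpaired * unpaired
    }
  }
  e
}
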