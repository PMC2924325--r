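#' @include AllClasses.R AllGenerics.R
NULL

#' Construct an RNA sequence
#'
#' Accepts RNA or DNA text (T is normalised to U, case is normalised to
#' upper) or a Biostrings XString/XStringSet of length one. Ambiguity
#' codes and gaps are rejected with the offending position.
#'
#' @param x character scalar, or a Biostrings object.
#' @param id sequence identifier; defaults to the name of `x` when
#'   present, otherwise "seq".
#' @return an [RnaSequence].
#' @examples
#' rnaSequence("GACTT", id = "demo")  # DNA accepted, T -> U
#' @export
rnaSequence <- function(x, id = NULL) {
  if (is(x, "RnaSequence")) return(x)
  if (is(x, "XStringSet")) {
    stopifnot(length(x) == 1L)
    if (is.null(id) && !is.null(names(x))) id <- names(x)[1]
    x <- as.character(x[[1]])
  } else if (is(x, "XString")) {
    x <- as.character(x)
  }
  stopifnot(is.character(x), length(x) == 1L)
  if (is.null(id)) id <- "seq"
  res <- chartr("t", "u", chartr("T", "U", toupper(x)))
  new("RnaSequence", id = as.character(id), residues = res)
}

#' @describeIn rnaSequence sequence length (number of residues).
#' @export
setMethod("length", "RnaSequence", function(x) nchar(x@residues))

#' @rdname seqId
#' @export
setMethod("seqId", "RnaSequence", function(x) x@id)

#' @rdname residues
#' @export
setMethod("residues", "RnaSequence", function(x) x@residues)

setMethod("show", "RnaSequence", function(object) {
  n <- length(object)
  s <- object@residues
  if (n > 60L) s <- paste0(substr(s, 1, 57), "...")
  cat(sprintf("RnaSequence '%s' (%d nt)\n  %s\n", object@id, n, s))
})

# residue vector / integer codes (A=0, C=1, G=2, U=3)
.resVector <- function(seq) strsplit(residues(seq), "", fixed = TRUE)[[1]]
.resCodes <- function(seq) {
  match(.resVector(seq), RNA_BASES) - 1L
}
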