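#' @include AllClasses.R
NULL

#' Evaluate an expression under a local RNG seed
#'
#' Applies `set.seed(seed)` for the duration of `expr` and restores the
#' caller's RNG state afterwards, so seeded package operations do not
#' disturb the session stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @export
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(),
                    inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# atomic write: compose content at a temp path, then rename into place
.writeAtomic <- function(path, writer) {
  tmp <- tempfile(tmpdir = dirname(path))
  on.exit(if (file.exists(tmp)) unlink(tmp))
  writer(tmp)
  if (!file.rename(tmp, path)) {
    file.copy(tmp, path, overwrite = TRUE)
    unlink(tmp)
  }
  invisible(path)
}

# fixed float formatting for byte-reproducible tabular output
.fmt6 <- function(x) sprintf("%.6g", x)
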