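#' @include AllClasses.R
NULL

#' Read an energy-parameter configuration file
#'
#' Parses the key-value parameter schema documented in the bundled
#' default set (see `system.file("extdata", "energy_params.txt",
#' package = "riboSnitch")`): stacking energies per pair step,
#' length-dependent hairpin/bulge/interior-loop penalties, a linear
#' multiloop model, the minimum hairpin loop size, and the thermodynamic
#' constants. The stacking table must satisfy the strand-reversal
#' symmetry E(XY on WZ) = E(ZW on YX).
#'
#' @param path path to a parameter file.
#' @return an [EnergyModel].
#' @export
readEnergyParams <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  toks <- strsplit(lines, "[[:space:]]+")
  key1 <- function(k) {
    hit <- which(vapply(toks, function(t) t[1] == k, logical(1)))
    if (length(hit) != 1L) stop("parameter '", k, "' must appear exactly once")
    toks[[hit]][-1]
  }
  num1 <- function(k) as.numeric(key1(k))
  loopTable <- function(k) {
    rows <- toks[vapply(toks, function(t) t[1] == k, logical(1))]
    len <- vapply(rows, function(t) as.integer(t[2]), integer(1))
    e <- vapply(rows, function(t) as.numeric(t[3]), numeric(1))
    if (anyDuplicated(len)) stop("duplicate ", k, " loop length")
    out <- e[order(len)]
    names(out) <- sort(len)
    if (!identical(as.integer(names(out)),
                   seq(min(len), max(len))))
      stop(k, " table must cover a contiguous range of loop lengths")
    out
  }
  allowed <- key1("allowed_pairs")
  stack <- matrix(NA_real_, 6, 6,
                  dimnames = list(CANONICAL_PAIRS, CANONICAL_PAIRS))
  srows <- toks[vapply(toks, function(t) t[1] == "stack", logical(1))]
  for (t in srows) stack[t[2], t[3]] <- as.numeric(t[4])
  sub <- stack[allowed, allowed, drop = FALSE]
  if (any(is.na(sub))) stop("stack table incomplete for allowed pairs")
  stack[is.na(stack)] <- 0
  rev2 <- function(p) paste0(substr(p, 2, 2), substr(p, 1, 1))
  for (o in allowed) for (i in allowed)
    if (abs(stack[o, i] - stack[rev2(i), rev2(o)]) > 1e-9)
      stop("stack table violates strand-reversal symmetry at ", o, "/", i)

  canon <- paste(lines[order(lines)], collapse = "\n")
  tmp <- tempfile()
  writeLines(canon, tmp)
  dg <- unname(tools::md5sum(tmp))
  unlink(tmp)

  new("EnergyModel",
      allowedPairs = allowed, stack = stack,
      hairpin = loopTable("hairpin"), bulge = loopTable("bulge"),
      internal = loopTable("internal"),
      multiloopOffset = num1("multiloop_offset"),
      multiloopBranch = num1("multiloop_branch"),
      multiloopUnpaired = num1("multiloop_unpaired"),
      minHairpin = as.integer(num1("min_hairpin_loop")),
      maxInteriorUnpaired = as.integer(num1("max_interior_unpaired")),
      extrapolationCoeff = num1("loop_extrapolation_coeff"),
      temperature = num1("temperature"),
      gasConstant = num1("gas_constant"),
      version = key1("param_set_version"), digest = dg)
}

.modelCache <- new.env(parent = emptyenv())

#' The bundled default energy model
#'
#' @return the [EnergyModel] parsed from the packaged parameter set
#'   (cached after the first call).
#' @export
defaultEnergyModel <- function() {
  if (is.null(.modelCache$default)) {
    path <- system.file("extdata", "energy_params.txt",
                        package = "riboSnitch")
    .modelCache$default <- readEnergyParams(path)
  }
  .modelCache$default
}

#' Thermal energy R*T of a model
#' @param model an [EnergyModel].
#' @return R*T in kcal/mol.
#' @export
thermalEnergy <- function(model) model@gasConstant * model@temperature

#' Loop penalty with long-loop extrapolation
#'
#' Looks up the tabulated penalty for a hairpin, bulge or interior loop
#' of the given length; beyond the table, extrapolates as
#' E(Lmax) + c * R*T * ln(l / Lmax).
#'
#' @param model an [EnergyModel].
#' @param type "hairpin", "bulge" or "internal".
#' @param len loop length (total unpaired bases).
#' @return energy in kcal/mol.
#' @export
loopEnergy <- function(model, type = c("hairpin", "bulge", "internal"),
                       len) {
  type <- match.arg(type)
  tab <- slot(model, type)
  lens <- as.integer(names(tab))
  lmax <- max(lens)
  out <- numeric(length(len))
  small <- len <= lmax
  if (any(len < min(lens))) stop("loop shorter than the tabulated minimum")
  out[small] <- tab[as.character(len[small])]
  if (any(!small))
    out[!small] <- tab[as.character(lmax)] +
      model@extrapolationCoeff * thermalEnergy(model) *
      log(len[!small] / lmax)
  unname(out)
}

setMethod("show", "EnergyModel", function(object) {
  cat(sprintf(paste0(
    "EnergyModel (simplified nearest-neighbour), version %s\n",
    "  pairs: %s; min hairpin loop %d; interior cap %d\n",
    "  T = %.2f K, R*T = %.4f kcal/mol; digest %s\n"),
    object@version, paste(object@allowedPairs, collapse = " "),
    object@minHairpin, object@maxInteriorUnpaired,
    object@temperature, thermalEnergy(object), object@digest))
})

# tables handed to the C++ engine; loop vectors precomputed out to the
# longest loop the sequence can form
.modelTables <- function(model, n) {
  pt <- matrix(-1L, 4, 4, dimnames = list(RNA_BASES, RNA_BASES))
  for (k in seq_along(model@allowedPairs)) {
    p <- model@allowedPairs[k]
    pt[substr(p, 1, 1), substr(p, 2, 2)] <- k - 1L
  }
  stack <- model@stack[model@allowedPairs, model@allowedPairs,
                       drop = FALSE]
  full <- matrix(0, 6, 6)
  full[seq_along(model@allowedPairs), seq_along(model@allowedPairs)] <-
    stack
  lmax <- max(n, 3L)
  list(pt = pt,
       stack = full,
       hairpin = loopEnergy(model, "hairpin",
                            pmax(seq_len(lmax), model@minHairpin)),
       bulge = loopEnergy(model, "bulge", seq_len(lmax)),
       internal = loopEnergy(model, "internal", pmax(seq_len(lmax), 2L)),
       multiloop = c(model@multiloopOffset, model@multiloopBranch,
                     model@multiloopUnpaired),
       h = model@minHairpin,
       maxloop = model@maxInteriorUnpaired,
       rt = thermalEnergy(model))
}

.pairAllowed <- function(model, a, b) {
  paste0(a, b) %in% model@allowedPairs
}
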