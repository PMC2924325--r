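#' @include AllClasses.R rna-sequence.R structure.R snpfold.R
NULL

#' Read RNA (or DNA) sequences from FASTA
#'
#' Standard multi-record FASTA via Biostrings; case is normalised to
#' upper and T to U. Any residue outside A, C, G, U (after
#' normalisation) is an error naming the record and offset.
#'
#' @param path readable FASTA file.
#' @return list of [RnaSequence] in file order.
#' @export
readRnaFasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("no FASTA records in ", path)
  ids <- sub("\\s.*$", "", names(set))
  lapply(seq_along(set), function(k)
    rnaSequence(as.character(set[[k]]), id = ids[k]))
}

#' Write sequences to FASTA
#'
#' @param seqs list of [RnaSequence] (or a single one).
#' @param path output file.
#' @return invisibly, the path.
#' @export
writeRnaFasta <- function(seqs, path) {
  if (is(seqs, "RnaSequence")) seqs <- list(seqs)
  .writeAtomic(path, function(tmp) {
    con <- file(tmp, "w")
    on.exit(close(con))
    for (s in seqs)
      writeLines(c(paste0(">", seqId(s)), residues(s)), con)
  })
}

# provenance comment lines carried by every tabular output
.provenanceHeader <- function(engine, digest, seeds = NULL) {
  out <- c(sprintf("# engine: %s", engine),
           sprintf("# energy_param_digest: %s", digest))
  if (!is.null(seeds))
    out <- c(out, sprintf("# seeds: %s", paste(seeds, collapse = " ")))
  out
}

#' Write a base-pair probability matrix as TSV
#'
#' @param bppm a [BasePairProbMatrix].
#' @param path output file.
#' @param model the [EnergyModel] that produced it (for the provenance
#'   header).
#' @param format "sparse" for (i, j, probability) upper-triangle rows,
#'   "dense" for the full square matrix.
#' @return invisibly, the path.
#' @export
writeBppmTsv <- function(bppm, path, model = defaultEnergyModel(),
                         format = c("sparse", "dense")) {
  format <- match.arg(format)
  P <- pairingProbabilities(bppm)
  n <- nrow(P)
  .writeAtomic(path, function(tmp) {
    con <- file(tmp, "w")
    on.exit(close(con))
    writeLines(.provenanceHeader("internal", model@digest), con)
    if (format == "sparse") {
      writeLines("i\tj\tprobability", con)
      for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n))
        if (P[i, j] > 0)
          writeLines(sprintf("%d\t%d\t%s", i, j, .fmt6(P[i, j])), con)
    } else {
      writeLines(paste(c("pos", seq_len(n)), collapse = "\t"), con)
      for (i in seq_len(n))
        writeLines(paste(c(i, .fmt6(P[i, ])), collapse = "\t"), con)
    }
  })
}

#' Write a mutation scan as TSV
#'
#' One row per scanned mutation with its tie-inclusive rank and
#' empirical p-value; deterministic formatting, so identical scans give
#' byte-identical files.
#'
#' @param scan a [MutationScanResult].
#' @param path output file.
#' @return invisibly, the path.
#' @export
writeScanTsv <- function(scan, path) {
  tab <- correlations(scan)
  rank <- vapply(tab$correlation, function(r)
    sum(tab$correlation <= r), numeric(1))
  .writeAtomic(path, function(tmp) {
    con <- file(tmp, "w")
    on.exit(close(con))
    writeLines(.provenanceHeader(scan@engine, scan@paramDigest), con)
    writeLines(paste(c("mutation", "position", "wild", "variant",
                       "correlation", "rank", "p_value"),
                     collapse = "\t"), con)
    writeLines(sprintf("%s\t%d\t%s\t%s\t%s\t%d\t%s",
                       tab$mutation, tab$position, tab$wild,
                       tab$variant, .fmt6(tab$correlation), rank,
                       .fmt6(rank / nrow(tab))), con)
  })
}

#' Write the 4 x n scan heat map as TSV
#'
#' Rows A, C, G, U; wild-type cells are written as ".".
#'
#' @inheritParams writeScanTsv
#' @return invisibly, the path.
#' @export
writeHeatmapTsv <- function(scan, path) {
  hm <- heatMap(scan)
  .writeAtomic(path, function(tmp) {
    con <- file(tmp, "w")
    on.exit(close(con))
    writeLines(.provenanceHeader(scan@engine, scan@paramDigest), con)
    writeLines(paste(c("base", seq_len(ncol(hm))), collapse = "\t"),
               con)
    for (b in rownames(hm)) {
      cells <- ifelse(is.na(hm[b, ]), ".", .fmt6(hm[b, ]))
      writeLines(paste(c(b, cells), collapse = "\t"), con)
    }
  })
}

#' Write projected ensemble coordinates as TSV
#'
#' @param projections list of [PcaProjection]s.
#' @param summary optional [ClusterSummary] over the same projections;
#'   adds a cluster column.
#' @param path output file.
#' @param seeds seeds to record in the provenance header.
#' @param model the [EnergyModel] used (for the provenance header).
#' @return invisibly, the path.
#' @export
writeProjectionTsv <- function(projections, path, summary = NULL,
                               seeds = NULL,
                               model = defaultEnergyModel()) {
  .writeAtomic(path, function(tmp) {
    con <- file(tmp, "w")
    on.exit(close(con))
    writeLines(.provenanceHeader("internal", model@digest, seeds), con)
    writeLines("sequence_label\tstructure_index\tpc1\tpc2\tcluster", con)
    for (p in seq_along(projections)) {
      pr <- projections[[p]]
      cl <- if (is.null(summary)) rep(NA_integer_, nrow(pr@coords))
            else summary@assignments[[p]]
      writeLines(sprintf("%s\t%d\t%s\t%s\t%s", pr@label,
                         seq_len(nrow(pr@coords)),
                         .fmt6(pr@coords[, 1]), .fmt6(pr@coords[, 2]),
                         ifelse(is.na(cl), ".", as.character(cl))), con)
    }
  })
}

#' Write cluster occupancies as TSV
#'
#' One row per sequence, one column per cluster, fractions of sampled
#' structures.
#'
#' @param summary a [ClusterSummary].
#' @param path output file.
#' @param seeds seeds to record in the provenance header.
#' @param model the [EnergyModel] used (for the provenance header).
#' @return invisibly, the path.
#' @export
writeOccupancyTsv <- function(summary, path, seeds = NULL,
                              model = defaultEnergyModel()) {
  occ <- occupancy(summary)
  .writeAtomic(path, function(tmp) {
    con <- file(tmp, "w")
    on.exit(close(con))
    writeLines(.provenanceHeader("internal", model@digest, seeds), con)
    writeLines(paste(c("sequence_label", colnames(occ)),
                     collapse = "\t"), con)
    for (r in seq_len(nrow(occ)))
      writeLines(paste(c(rownames(occ)[r], .fmt6(occ[r, ])),
                       collapse = "\t"), con)
  })
}

#' Write structures as dot-bracket lines
#'
#' @param structures list of [SecondaryStructure] (or one).
#' @param path output file.
#' @param labels optional one label per structure (written as FASTA-like
#'   headers).
#' @return invisibly, the path.
#' @export
writeDotBracket <- function(structures, path, labels = NULL) {
  if (is(structures, "SecondaryStructure"))
    structures <- list(structures)
  .writeAtomic(path, function(tmp) {
    con <- file(tmp, "w")
    on.exit(close(con))
    for (k in seq_along(structures)) {
      if (!is.null(labels)) writeLines(paste0(">", labels[k]), con)
      writeLines(toDotBracket(structures[[k]]), con)
    }
  })
}

#' Write a machine-readable run manifest
#'
#' Records the inputs, seeds, engine, energy-parameter digest and
#' package version of a run as JSON, so every output directory is
#' self-describing.
#'
#' @param path output JSON file.
#' @param command the subcommand or function that ran.
#' @param inputs named list of input descriptors.
#' @param seeds named or unnamed seed collection.
#' @param engine engine selector used.
#' @param model the [EnergyModel] used.
#' @param outputs character vector of files written.
#' @return invisibly, the path.
#' @export
writeRunManifest <- function(path, command, inputs = list(),
                             seeds = list(), engine = "internal",
                             model = defaultEnergyModel(),
                             outputs = character(0)) {
  manifest <- list(
    command = command, inputs = inputs, seeds = seeds, engine = engine,
    energy_param_version = model@version,
    energy_param_digest = model@digest,
    package = "riboSnitch",
    package_version = as.character(utils::packageVersion("riboSnitch")),
    outputs = outputs)
  .writeAtomic(path, function(tmp)
    jsonlite::write_json(manifest, tmp, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA))
}

#' Run configuration
#'
#' Bundles the knobs of a full analysis run - engine selector, energy
#' parameter file, seeds, sample sizes, output directory, log level -
#' into one object that round-trips losslessly through JSON, so a run
#' can be re-executed from its recorded configuration. Seeds must be
#' explicit; auto-generating them is the caller's job (and should be
#' logged).
#'
#' @param engine "internal" or "external".
#' @param paramsPath path to an energy-parameter file, or NA for the
#'   bundled default set.
#' @param seeds named integer vector of all seeds the run will use.
#' @param samples structures sampled per sequence.
#' @param basisSubsample per-sequence subsample used for the PCA basis.
#' @param k number of clusters.
#' @param outDir output directory.
#' @param logLevel one of debug, info, warn, error.
#' @return a [RunConfig].
#' @export
runConfig <- function(engine = "internal", paramsPath = NA_character_,
                      seeds = c(run = 1L), samples = 5000L,
                      basisSubsample = 1000L, k = 3L, outDir = ".",
                      logLevel = "info") {
  stopifnot(engine %in% c("internal", "external"),
            length(seeds) >= 1L, !is.null(names(seeds)),
            all(nzchar(names(seeds))), !anyNA(seeds),
            logLevel %in% c("debug", "info", "warn", "error"))
  new("RunConfig", engine = engine,
      paramsPath = as.character(paramsPath),
      seeds = vapply(seeds, as.integer, integer(1)),
      samples = as.integer(samples),
      basisSubsample = as.integer(basisSubsample), k = as.integer(k),
      outDir = outDir, logLevel = logLevel)
}

#' @describeIn runConfig write a configuration as JSON.
#' @param config a [RunConfig].
#' @param path JSON file path.
#' @export
writeRunConfig <- function(config, path) {
  stopifnot(is(config, "RunConfig"))
  payload <- list(engine = config@engine,
                  params_path = config@paramsPath,
                  seeds = as.list(config@seeds),
                  samples = config@samples,
                  basis_subsample = config@basisSubsample,
                  k = config@k, out_dir = config@outDir,
                  log_level = config@logLevel)
  .writeAtomic(path, function(tmp)
    jsonlite::write_json(payload, tmp, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA))
}

#' @describeIn runConfig read a configuration back from JSON.
#' @export
readRunConfig <- function(path) {
  p <- jsonlite::read_json(path)
  runConfig(engine = p$engine,
            paramsPath = if (is.null(p$params_path)) NA_character_
                         else p$params_path,
            seeds = unlist(p$seeds), samples = p$samples,
            basisSubsample = p$basis_subsample, k = p$k,
            outDir = p$out_dir, logLevel = p$log_level)
}
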