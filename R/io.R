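# Run artifacts: CSV time series, FASTA output-cell dump, a structured
# summary record, the antigen conservation ledger, and a run manifest
# sufficient to reproduce the run bit-for-bit.

file_md5 <- function(obj) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(obj, f, version = 2)
  unname(tools::md5sum(f))
}

#' Hash of an antigen (geometry + residues)
#' @param antigen a `lattice_antigen`.
#' @return md5 string.
#' @export
antigen_hash <- function(antigen) {
  file_md5(list(pos = antigen$positions, res = antigen$residues))
}

#' Write all artifacts of a simulation run
#'
#' Writes `timeseries.csv` (the metrics table), `outputs.fasta` (egressed
#' sequences; headers carry the mutation count and per-domain affinities),
#' `ledger.csv` (the antigen conservation audit columns), `summary.json`,
#' and `manifest.json` into `dir`.
#'
#' @param sim a `gc_sim`.
#' @param dir output directory (created if needed).
#' @param antigen_set the antigen set the run used (hashed in the manifest);
#'   optional.
#' @param founder_pool the founder pool the run used (hashed); optional.
#' @return the manifest, invisibly.
#' @export
write_gc_run <- function(sim, dir, antigen_set = NULL, founder_pool = NULL) {
  stopifnot(inherits(sim, "gc_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tsf <- file.path(dir, "timeseries.csv")
  write.csv(sim$metrics, tsf, row.names = FALSE)
  ledger_cols <- c("time", "antigen_on_fdc", "antigen_in_cells",
                   "antigen_removed")
  ledf <- file.path(dir, "ledger.csv")
  write.csv(sim$metrics[, ledger_cols], ledf, row.names = FALSE)
  faf <- file.path(dir, "outputs.fasta")
  if (nrow(sim$outputs) > 0) {
    affcols <- grep("^aff_", names(sim$outputs), value = TRUE)
    ids <- sprintf("output_%d|t=%.2f|mutations=%d|%s",
                   seq_len(nrow(sim$outputs)), sim$outputs$time,
                   sim$outputs$mutations,
                   apply(sim$outputs[, affcols, drop = FALSE], 1, function(r)
                     paste(sprintf("%s=%.4g", affcols, r), collapse = "|")))
    seqinr::write.fasta(as.list(sim$outputs$seq), names = ids,
                        file.out = faf, as.string = TRUE)
  } else {
    writeLines(character(0), faf)
  }
  sumf <- file.path(dir, "summary.json")
  jsonlite::write_json(sim$state, sumf, auto_unbox = TRUE, digits = NA)
  manifest <- list(
    package = "latticeGC",
    version = as.character(utils::packageVersion("latticeGC")),
    written = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = unclass(sim$config),
    seed = sim$config$seed,
    antigen_ids = sim$antigen_ids,
    antigen_hashes = if (!is.null(antigen_set))
      lapply(antigen_set$domains, antigen_hash) else NULL,
    founder_pool_hash = if (!is.null(founder_pool))
      file_md5(founder_pool$pool) else NULL,
    files = c("timeseries.csv", "ledger.csv", "outputs.fasta",
              "summary.json"))
  # written last and atomically: the manifest's presence marks a complete run
  mf <- file.path(dir, "manifest.json")
  tmp <- paste0(mf, ".tmp")
  jsonlite::write_json(manifest, tmp, auto_unbox = TRUE, digits = NA,
                       null = "null")
  file.rename(tmp, mf)
  invisible(manifest)
}
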