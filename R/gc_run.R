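# Running GC simulations.  The compiled engine holds the full lattice state;
# these wrappers assemble its inputs (pose sets per antigen domain, founder
# pool, configuration), run it, and repackage metrics/outputs as data frames.

engine_inputs <- function(config, antigen_set, founder_pool, U) {
  stopifnot(inherits(config, "gc_config"))
  if (inherits(antigen_set, "lattice_antigen"))
    antigen_set <- build_antigen_set(list(antigen_set),
                                     total_dose = config$antigen_total)
  stopifnot(inherits(antigen_set, "antigen_set"))
  # the antigen set's dose is authoritative for the run
  config$antigen_total <- antigen_set$total_dose
  ids <- vapply(antigen_set$domains, `[[`, character(1), "id")
  poses <- lapply(antigen_set$domains, enumerate_poses, L = config$bcr_length,
                  min_contacts = config$min_contacts)
  stopifnot(inherits(founder_pool, "founder_pool"))
  dom <- match(founder_pool$pool$antigen, ids)
  if (anyNA(dom))
    stop("founder pool references antigen(s) absent from the set: ",
         paste(unique(founder_pool$pool$antigen[is.na(dom)]), collapse = ", "))
  list(ids = ids, ptrs = lapply(poses, `[[`, "ptr"),
       pool_seqs = aa_encode(founder_pool$pool$seq), pool_dom = dom,
       U = unclass(U), config = config)
}

#' Number of divisions attributed after Tfh selection
#'
#' Hill map of internalized antigen units to the division count granted on
#' recycling: `Nmin + round((Nmax - Nmin) * a^h / (a^h + K^h))`.  Monotone
#' nondecreasing and bounded in `[Nmin, Nmax]`; `a = 0` gives `Nmin`.
#'
#' @param a internalized antigen units (vectorized, nonnegative).
#' @param nmin,nmax division bounds (defaults 1 and 6).
#' @param K half-saturation in antigen units (default 9).
#' @param h Hill coefficient (default 2).
#' @return integer vector of division counts.
#' @export
divisions_from_antigen <- function(a, nmin = 1, nmax = 6, K = 9, h = 2) {
  stopifnot(all(a >= 0), K > 0, h > 0, nmax >= nmin)
  cpp_divisions_from_antigen(as.integer(a), nmin, nmax, K, h)
}

#' Draw B-cell division (cell-cycle) times
#'
#' The simulator's division-time sampler: Normal(mean, sd) truncated to
#' positive values, drawn from the engine's own seeded RNG.
#'
#' @param n number of draws.
#' @param mean mean cycle length in hours (default 7.5).
#' @param sd standard deviation in hours (default 1.25).
#' @param seed engine seed.
#' @return numeric vector of `n` positive durations.
#' @export
draw_cycle_times <- function(n, mean = 7.5, sd = 1.25, seed = 1) {
  stopifnot(n >= 1, mean > 0, sd > 0)
  cpp_draw_cycle_times(as.integer(n), mean, sd, seed)
}

#' Initialize a germinal center without running it
#'
#' Builds the full lattice state (agent placement, FDC network, antigen
#' distribution, guidance fields) and returns its summary — useful for
#' inspecting the initial condition.
#'
#' @param config a `gc_config`.
#' @param antigen_set an `antigen_set` (or single `lattice_antigen`).
#' @param founder_pool a `founder_pool` whose antigen labels match the set.
#' @param U contact potential.
#' @return a list with the engine handle (`ptr`), placement summary
#'   (`state`), and per-domain antigen amounts on the FDCs.
#' @export
gc_initialize <- function(config, antigen_set, founder_pool,
                          U = default_potential()) {
  inp <- engine_inputs(config, antigen_set, founder_pool, U)
  ptr <- cpp_gc_new(unclass(inp$config), inp$ptrs, inp$U, inp$pool_seqs,
                    inp$pool_dom, numeric(0))
  list(ptr = ptr, state = cpp_gc_state(ptr),
       antigen_per_domain = setNames(
         cpp_gc_antigen_per_domain(ptr)$on_fdc_per_domain, inp$ids),
       antigen_ids = inp$ids)
}

#' Run a germinal center simulation
#'
#' Advances the agent-based model from time 0 to `sim_days` x 24 h in steps
#' of `dt`, recording population metrics on the snapshot cadence.  Runs are
#' deterministic given the configuration (which includes the seed).
#'
#' @param config a `gc_config`.
#' @param antigen_set an `antigen_set` (or single `lattice_antigen`).
#' @param founder_pool a `founder_pool` whose antigen labels match the set.
#' @param U contact potential.
#' @param cell_snapshot_times numeric vector of times (h) at which a full
#'   per-cell table is captured (e.g. `13 * 24` for a day-13 affinity
#'   scatter).
#' @return a `gc_sim` object: `metrics` (one row per snapshot time),
#'   `outputs` (one row per egressed output cell), `cells` (final live-cell
#'   table), `snapshots` (per-cell tables at `cell_snapshot_times`),
#'   `state` (final engine summary), `antigen_ids`, and `config`.
#' @examples
#' \donttest{
#' set.seed(1)
#' ag <- randomize_residues(generate_structure(8, compactness = 2), id = "A1")
#' cfg <- gc_toy_config(seed = 7, sim_days = 2)
#' pool <- generate_founder_pool(ag, pool_total = 50, min_affinity = 0,
#'                               L = cfg$bcr_length)
#' sim <- gc_run(cfg, ag, pool)
#' tail(sim$metrics[, c("time", "n_bcells", "outputs_cum")])
#' }
#' @export
gc_run <- function(config, antigen_set, founder_pool,
                   U = default_potential(), cell_snapshot_times = numeric(0)) {
  inp <- engine_inputs(config, antigen_set, founder_pool, U)
  ptr <- cpp_gc_new(unclass(inp$config), inp$ptrs, inp$U, inp$pool_seqs,
                    inp$pool_dom, as.numeric(cell_snapshot_times))
  cpp_gc_run(ptr, config$sim_days * 24)
  raw <- cpp_gc_metrics(ptr)
  affs <- raw$mean_aff_domain
  raw$mean_aff_domain <- NULL
  metrics <- as.data.frame(raw, stringsAsFactors = FALSE)
  for (d in seq_along(affs))
    metrics[[paste0("mean_aff_", inp$ids[d])]] <- affs[[d]]
  out <- cpp_gc_outputs(ptr)
  aff <- out$aff
  out$aff <- NULL
  outputs <- as.data.frame(out, stringsAsFactors = FALSE)
  for (d in seq_along(inp$ids))
    outputs[[paste0("aff_", inp$ids[d])]] <- aff[, d]
  structure(list(metrics = metrics, outputs = outputs,
                 cells = cpp_gc_cells(ptr),
                 snapshots = cpp_gc_snapshots(ptr),
                 state = cpp_gc_state(ptr), antigen_ids = inp$ids,
                 config = config),
            class = "gc_sim")
}

#' @export
print.gc_sim <- function(x, ...) {
  st <- x$state
  cat("GC simulation: ", st$time / 24, " days, ", length(x$antigen_ids),
      " domain(s) [", paste(x$antigen_ids, collapse = ", "), "]\n", sep = "")
  cat("  final B cells: ", st$n_bcells, " | founders: ", st$founders_arrived,
      " | outputs: ", nrow(x$outputs), " | ASC: ", st$asc, "\n", sep = "")
  cat("  antigen ledger: ", st$antigen_on_fdc, " on FDC + ",
      st$antigen_in_cells, " in cells + ", st$antigen_removed,
      " removed = ", st$antigen_total, "\n", sep = "")
  invisible(x)
}

#' Run replicate GC simulations and aggregate metrics
#'
#' Runs `n` independent simulations that differ only in seed (config seed +
#' replicate index) and returns per-time mean and standard deviation of all
#' numeric metrics on the common snapshot grid, plus the individual runs.
#'
#' @param config a `gc_config`; replicate `i` runs with seed
#'   `config$seed + i - 1`.
#' @param antigen_set an `antigen_set` (or single `lattice_antigen`).
#' @param founder_pool a `founder_pool`, shared across replicates.
#' @param n number of replicates (default 10).
#' @param U contact potential.
#' @param keep_runs logical; keep the individual `gc_sim` objects.
#' @return a `gc_replicates` object with `mean`, `sd` (data.frames on the
#'   snapshot grid) and optionally `runs`.
#' @export
gc_run_replicates <- function(config, antigen_set, founder_pool, n = 10L,
                              U = default_potential(), keep_runs = FALSE) {
  stopifnot(n >= 1)
  runs <- vector("list", n)
  for (i in seq_len(n)) {
    cfg_i <- config
    cfg_i$seed <- config$seed + i - 1
    runs[[i]] <- gc_run(cfg_i, antigen_set, founder_pool, U = U)
  }
  num_cols <- names(runs[[1]]$metrics)[vapply(runs[[1]]$metrics, is.numeric,
                                              logical(1))]
  grid <- runs[[1]]$metrics$time
  arr <- sapply(runs, function(r) as.matrix(r$metrics[, num_cols]),
                simplify = "array")
  mu <- apply(arr, c(1, 2), mean)
  sdev <- apply(arr, c(1, 2), stats::sd)
  if (n == 1) sdev[] <- 0
  structure(list(mean = as.data.frame(mu), sd = as.data.frame(sdev),
                 time = grid, n = n,
                 runs = if (keep_runs) runs else NULL,
                 antigen_ids = runs[[1]]$antigen_ids),
            class = "gc_replicates")
}

#' @export
print.gc_replicates <- function(x, ...) {
  cat("GC replicate set: n = ", x$n, ", ", length(x$time),
      " time points, domains [", paste(x$antigen_ids, collapse = ", "),
      "]\n", sep = "")
  invisible(x)
}
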