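# Observables over simulation state: population metrics, per-cell affinity
# scatters between two domains, the census of optimal binding conformations,
# SHM distributions, and affinity normalization against a reference
# condition.

#' Compute a metrics row from a per-cell table
#'
#' Aggregates a per-cell snapshot (as returned in `gc_sim$cells` or
#' `gc_sim$snapshots`) into the population observables recorded by the
#' simulation: population size, per-domain and max-over-domains mean
#' affinity, and sequence diversity.  Affinity means are over living GC B
#' cells; an empty table yields zero counts and `NA` means.
#'
#' @param cells a per-cell data.frame with `seq` and `aff_d*` columns.
#' @return a one-row data.frame.
#' @export
record_snapshot <- function(cells) {
  affcols <- grep("^aff_d[0-9]+$", names(cells), value = TRUE)
  n <- nrow(cells)
  row <- data.frame(n_bcells = n,
                    diversity = length(unique(cells$seq)))
  for (k in affcols)
    row[[paste0("mean_", k)]] <- if (n > 0) mean(cells[[k]]) else NA_real_
  row$mean_aff_max <- if (n > 0) {
    if (length(affcols) == 1) mean(cells[[affcols]])
    else mean(do.call(pmax, cells[affcols]))
  } else NA_real_
  row
}

#' Per-cell affinity scatter between two antigen domains
#'
#' One record per living GC B cell with its affinity to each of two domains,
#' as captured at a snapshot time (the late-phase day-13 snapshot in the
#' standard experiment designs).  The domains need not have been present in
#' the simulation: affinities are recomputed by docking each distinct
#' sequence against the requested antigens, so the scatter doubles as a
#' cross-reactivity readout.
#'
#' @param sim a `gc_sim` run with `cell_snapshot_times` covering `time`, or
#'   a per-cell data.frame.
#' @param domain_pair list of two `lattice_antigen` objects.
#' @param time snapshot time in hours (default day 13); ignored when `sim`
#'   is already a per-cell table.
#' @param U contact potential.
#' @param s stabilization factor.
#' @param params affinity conversion parameters.
#' @param min_contacts forwarded to [enumerate_poses()].
#' @return data.frame with `id`, `seq`, and one affinity column per domain.
#' @export
affinity_scatter <- function(sim, domain_pair, time = 13 * 24,
                             U = default_potential(), s = 1.0,
                             params = affinity_params(), min_contacts = 1L) {
  stopifnot(length(domain_pair) == 2)
  cells <- snapshot_cells(sim, time)
  if (nrow(cells) == 0) {
    out <- data.frame(id = integer(0), seq = character(0))
    for (ag in domain_pair) out[[paste0("aff_", ag$id)]] <- numeric(0)
    return(out)
  }
  out <- cells[, c("id", "seq")]
  uniq <- unique(cells$seq)
  for (ag in domain_pair) {
    be <- binding_energy(uniq, ag, U = U, s = s, L = nchar(uniq[1]),
                         min_contacts = min_contacts, params = params)
    out[[paste0("aff_", ag$id)]] <- be$affinity[match(cells$seq, uniq)]
  }
  out
}

snapshot_cells <- function(sim, time) {
  if (is.data.frame(sim)) return(sim)
  stopifnot(inherits(sim, "gc_sim"))
  if (length(sim$snapshots) == 0)
    stop("simulation was run without cell snapshots; pass cell_snapshot_times")
  times <- vapply(sim$snapshots, function(s)
    if (nrow(s) > 0) s$time[1] else NA_real_, numeric(1))
  k <- which.min(abs(times - time))
  if (length(k) == 0 || is.na(times[k]) || abs(times[k] - time) > 1 + 1e-9)
    stop("no cell snapshot within 1 h of t = ", time, " h")
  sim$snapshots[[k]]
}

#' Census of optimal binding conformations
#'
#' Groups the distinct BCR sequences in a snapshot by the representative
#' pose of their energetically optimal binding conformation on one antigen
#' — the number of unique sequences binding the antigen through each
#' conformation.
#'
#' @param sim a `gc_sim` with cell snapshots, a per-cell data.frame, or a
#'   character vector of sequences.
#' @param antigen the `lattice_antigen` (or `pose_set`) to dock against.
#' @param time snapshot time in hours (where `sim` is a `gc_sim`).
#' @param U,s,min_contacts docking parameters.
#' @return data.frame with `pose_id`, `n_sequences`, and the pose geometry
#'   (`start_x/y/z`, `moves` as a dash-separated code string) for rendering;
#'   `n_sequences` sums to the number of distinct sequences.
#' @export
conformation_census <- function(sim, antigen, time = 13 * 24,
                                U = default_potential(), s = 1.0,
                                min_contacts = 1L) {
  seqs <- if (is.character(sim)) sim else snapshot_cells(sim, time)$seq
  seqs <- unique(seqs)
  if (length(seqs) == 0)
    return(data.frame(pose_id = numeric(0), n_sequences = integer(0)))
  poses <- if (inherits(antigen, "pose_set")) antigen
           else enumerate_poses(antigen, L = nchar(seqs[1]),
                                min_contacts = min_contacts)
  be <- binding_energy(seqs, poses, U = U, s = s)
  tab <- table(be$pose_id)
  census <- data.frame(pose_id = as.numeric(names(tab)),
                       n_sequences = as.integer(tab))
  prof <- pose_profiles(poses, be$profile[match(census$pose_id, be$pose_id)])
  census$start_x <- vapply(prof, function(p) p$start[1], numeric(1))
  census$start_y <- vapply(prof, function(p) p$start[2], numeric(1))
  census$start_z <- vapply(prof, function(p) p$start[3], numeric(1))
  census$moves <- vapply(prof, function(p) paste(p$moves, collapse = "-"),
                         character(1))
  census[order(-census$n_sequences), ]
}

#' Histogram of SHM counts in output cells
#'
#' @param outputs the `outputs` table of a `gc_sim` (or any data.frame with
#'   a `mutations` column).
#' @param cumulative logical; also return the integral (cumulative) form.
#' @return data.frame with `mutations`, `count` and (if requested)
#'   `cum_count`, sorted by mutation number.
#' @export
shm_histogram <- function(outputs, cumulative = TRUE) {
  mut <- if (is.data.frame(outputs)) outputs$mutations else outputs
  if (length(mut) == 0) {
    out <- data.frame(mutations = integer(0), count = integer(0))
    if (cumulative) out$cum_count <- integer(0)
    return(out)
  }
  tab <- table(factor(mut, levels = 0:max(mut)))
  out <- data.frame(mutations = as.integer(names(tab)),
                    count = as.integer(tab))
  if (cumulative) out$cum_count <- cumsum(out$count)
  out
}

#' Normalize an affinity series against a reference condition
#'
#' Element-wise ratio of a series to the mean of a reference series —
#' e.g. affinities to a domain normalized to the average affinity reached
#' when that domain is immunized alone.
#'
#' @param series numeric vector.
#' @param reference_series numeric vector whose mean is the denominator.
#' @return `series / mean(reference_series)`.
#' @export
normalize_affinity_to_reference <- function(series, reference_series) {
  m <- mean(reference_series, na.rm = TRUE)
  if (!is.finite(m) || m == 0)
    stop("reference series has zero or undefined mean")
  series / m
}
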