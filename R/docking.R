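# Exhaustive docking engine.  Enumeration is two-phase: all binding
# conformations (poses) of a length-L BCR around an antigen are enumerated
# once and reduced to sequence-independent contact profiles; scoring a BCR
# sequence is then a table-lookup sum over profiles.  Poses sharing a contact
# profile have identical energy for every sequence and are deduplicated, with
# the first pose in the canonical enumeration order (sorted by start node,
# then by move codes) kept as the representative.

#' Enumerate BCR binding conformations around an antigen
#'
#' Enumerates every self-avoiding chain of length `L` on the lattice that (i)
#' does not overlap an antigen node and (ii) makes at least `min_contacts`
#' non-covalent adjacencies with antigen nodes.  The result is cached per
#' (antigen geometry + residues, L, min_contacts) within the session.
#'
#' @param antigen a `lattice_antigen` object.
#' @param L BCR chain length (2..9).
#' @param min_contacts minimum number of BCR-antigen adjacencies for a pose
#'   to count as binding (default 1).
#' @param max_poses guard against runaway enumerations; the enumeration stops
#'   with an error if more than this many poses are found.
#' @param cache logical; reuse a previously enumerated set for the same key.
#' @return a `pose_set` object.
#' @export
enumerate_poses <- function(antigen, L = 9L, min_contacts = 1L,
                            max_poses = 2e8, cache = TRUE) {
  stopifnot(inherits(antigen, "lattice_antigen"))
  if (nrow(antigen$positions) < 1) stop("antigen is empty")
  if (L < 2) stop("BCR length must be at least 2")
  if (min_contacts < 1) stop("min_contacts must be >= 1")
  gkey <- geomset_key(antigen$positions, L, min_contacts)
  key <- paste0(gkey, "|", paste(antigen$residues, collapse = ""))
  if (cache && !is.null(.pose_cache[[key]])) return(.pose_cache[[key]])
  # stage 1: geometry enumeration, reused across residue reassignments
  gp <- .geom_cache[[gkey]]
  if (is.null(gp)) {
    gp <- cpp_enumerate_geometry(antigen$positions, as.integer(L),
                                 as.integer(min_contacts), max_poses)
    # the geometry stage dominates cost and is residue-independent: always keep
    .geom_cache[[gkey]] <- gp
  }
  # stage 2: merge geometric profiles under this residue assignment
  xptr <- cpp_project_poseset(gp, match(antigen$residues, AA_ALPHABET))
  info <- cpp_poseset_info(xptr)
  ps <- structure(list(ptr = xptr, antigen_id = antigen$id, key = key,
                       L = as.integer(L), min_contacts = as.integer(min_contacts),
                       n_profiles = info$n_profiles,
                       total_poses = info$total_poses),
                  class = "pose_set")
  if (cache) .pose_cache[[key]] <- ps
  ps
}

.pose_cache <- new.env(parent = emptyenv())
.geom_cache <- new.env(parent = emptyenv())

#' Clear the session pose-enumeration caches
#' @return invisibly, NULL.
#' @export
clear_pose_cache <- function() {
  rm(list = ls(.pose_cache), envir = .pose_cache)
  rm(list = ls(.geom_cache), envir = .geom_cache)
  invisible(NULL)
}

geomset_key <- function(positions, L, min_contacts) {
  paste0(L, "|", min_contacts, "|", paste(c(t(positions)), collapse = ","))
}

#' @export
print.pose_set <- function(x, ...) {
  cat("Pose set for antigen '", x$antigen_id, "': L = ", x$L,
      ", min_contacts = ", x$min_contacts, "\n", sep = "")
  cat(format(x$total_poses, big.mark = ","), "poses collapsing onto",
      format(x$n_profiles, big.mark = ","), "unique contact profiles\n")
  invisible(x)
}

#' Extract contact profiles from a pose set
#'
#' @param poses a `pose_set`.
#' @param idx 1-based profile indices.
#' @return a list with, per profile, the inter contacts (`inter_bcr` index,
#'   `inter_res` antigen residue letter), intra pairs, the number of poses
#'   sharing the profile and the representative pose (start node and move
#'   codes 1..6 for +x, -x, +y, -y, +z, -z).
#' @export
pose_profiles <- function(poses, idx) {
  stopifnot(inherits(poses, "pose_set"))
  out <- cpp_poseset_profiles(poses$ptr, as.integer(idx))
  lapply(out, function(p) {
    p$inter_res <- AA_ALPHABET[p$inter_res]
    p
  })
}

#' Energy of one contact profile for a given sequence
#'
#' `E = sum_inter U(seq[i], antigen residue) + s * sum_intra U(seq[i], seq[j])`,
#' where the intra sum runs over the pose's non-covalent intra-BCR contacts.
#'
#' @param seq BCR sequence (string of length L).
#' @param profile one element of [pose_profiles()].
#' @param U contact potential.
#' @param s stabilization factor applied to intra-BCR contacts.
#' @return energy in kT.
#' @export
profile_energy <- function(seq, profile, U = default_potential(), s = 1.0) {
  res <- strsplit(seq, "")[[1]]
  if (!all(res %in% AA_ALPHABET)) stop("unknown residue letter in sequence")
  e <- 0
  if (length(profile$inter_bcr) > 0) {
    if (max(profile$inter_bcr) > length(res))
      stop("sequence length does not match the profile's pose set")
    e <- e + sum(U[cbind(res[profile$inter_bcr], profile$inter_res)])
  }
  if (length(profile$intra_i) > 0) {
    if (max(profile$intra_j) > length(res))
      stop("sequence length does not match the profile's pose set")
    e <- e + s * sum(U[cbind(res[profile$intra_i], res[profile$intra_j])])
  }
  e
}

#' Optimal binding energy and affinity of BCR sequences against an antigen
#'
#' The binding energy is the minimum energy over all enumerated poses; ties
#' are broken in favor of the smallest pose index in the canonical order.
#'
#' @param seq character vector of BCR sequences (all of the pose set's L).
#' @param antigen a `lattice_antigen`, or a `pose_set` obtained from one.
#' @param U contact potential.
#' @param s stabilization factor for intra-BCR contacts (default 1).
#' @param L,min_contacts forwarded to [enumerate_poses()] when `antigen` is a
#'   `lattice_antigen`.
#' @param params affinity conversion parameters, see [affinity_params()].
#' @return a data.frame with columns `seq`, `energy` (kT), `affinity`,
#'   `pose_id` (1-based index of the optimal pose) and `profile`.
#' @export
binding_energy <- function(seq, antigen, U = default_potential(), s = 1.0,
                           L = NULL, min_contacts = 1L,
                           params = affinity_params()) {
  poses <- if (inherits(antigen, "pose_set")) antigen
           else enumerate_poses(antigen, L = if (is.null(L)) nchar(seq[1]) else L,
                                min_contacts = min_contacts)
  if (poses$n_profiles == 0)
    stop("antigen unbindable at min_contacts = ", poses$min_contacts)
  codes <- aa_encode(seq)
  if (ncol(codes) != poses$L)
    stop("sequence length ", ncol(codes), " does not match pose set L = ",
         poses$L)
  sc <- cpp_score_sequences(poses$ptr, codes, unclass(U), s)
  data.frame(seq = seq, energy = sc$energy,
             affinity = energy_to_affinity(sc$energy, params),
             pose_id = sc$pose, profile = sc$profile,
             stringsAsFactors = FALSE)
}

#' Affinity conversion parameters
#'
#' Energies E (kT) are mapped to unitless affinities.  In the default
#' `"strength"` mode, Aff = exp((Emax - E) / C): affinity increases as the
#' energy becomes more negative, equals 1 at E = Emax, lies in (0, 1) for
#' E > Emax, and exceeds 1 for E < Emax.  The `"literal"` mode applies the
#' opposite sign, Aff = exp((E - Emax) / C).
#'
#' @param Emax reference energy (default -100 kT).
#' @param C scale (default 2.8 kT); must be positive.
#' @param mode `"strength"` (default) or `"literal"`.
#' @return a list with class `affinity_params`.
#' @export
affinity_params <- function(Emax = -100, C = 2.8, mode = c("strength", "literal")) {
  if (C <= 0) stop("affinity scale C must be positive")
  structure(list(Emax = Emax, C = C, mode = match.arg(mode)),
            class = "affinity_params")
}

#' Convert binding energy to affinity
#'
#' @param E energy in kT (vectorized).
#' @param params see [affinity_params()].
#' @return unitless affinity, strictly monotone in `E`.
#' @examples
#' energy_to_affinity(-100)   # 1
#' energy_to_affinity(-74.2)  # ~1e-4, the founder filtering threshold
#' @export
energy_to_affinity <- function(E, params = affinity_params()) {
  if (params$mode == "strength") exp((params$Emax - E) / params$C)
  else exp((E - params$Emax) / params$C)
}

#' Convert affinity back to binding energy
#'
#' Exact inverse of [energy_to_affinity()] in the active mode.
#'
#' @param aff affinity, must be > 0 (vectorized).
#' @param params see [affinity_params()].
#' @return energy in kT.
#' @export
affinity_to_energy <- function(aff, params = affinity_params()) {
  if (any(aff <= 0)) stop("affinity must be positive")
  if (params$mode == "strength") params$Emax - params$C * log(aff)
  else params$Emax + params$C * log(aff)
}

#' Decode a representative pose into lattice positions
#'
#' @param profile one element of [pose_profiles()].
#' @return integer matrix of the pose's residue positions.
#' @export
pose_positions <- function(profile) {
  dirs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  pos <- matrix(0L, nrow = length(profile$moves) + 1, ncol = 3)
  pos[1, ] <- profile$start
  for (m in seq_along(profile$moves))
    pos[m + 1, ] <- pos[m, ] + dirs[profile$moves[m], ]
  pos
}
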