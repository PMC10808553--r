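# Naive BCR panels, the somatic hypermutation (SHM) operator, and founder
# pools.  Founders are rejection-sampled uniform sequences filtered by a
# minimum affinity to their assigned antigen (default 1e-4), with equal
# per-antigen quotas totalling `pool_total` (default 1000).

#' Random naive BCR panel
#'
#' @param n number of sequences.
#' @param L sequence length (default 9, the CDRH3 substring length used
#'   throughout).
#' @return character vector of `n` i.i.d. uniform sequences; reproducible
#'   under `set.seed()`.
#' @export
random_bcr_panel <- function(n, L = 9L) {
  stopifnot(n >= 1, L >= 1)
  m <- matrix(sample.int(20L, n * L, replace = TRUE), nrow = n)
  aa_decode(m)
}

#' Somatic hypermutation operator
#'
#' Each residue is independently replaced with probability `p` by a uniform
#' draw among the 19 other residues, so a "replacement" always changes the
#' residue and the number of changes is Binomial(L, p).  Multiple
#' simultaneous replacements are allowed.  With the default L = 9 and
#' p = 0.055 the mean number of replacements per application is
#' 9 x 0.055 = 0.495, i.e. about 0.5 mutations per division.
#'
#' @param seq character vector of sequences (recycled if `n` is given).
#' @param p per-residue replacement probability in `[0, 1]`.
#' @param n optional number of independent applications to `seq[1]`; when
#'   given, overrides `seq` recycling.
#' @return a list with `seqs` (mutated sequences) and `n_changes` (integer
#'   vector of replacement counts); reproducible under `set.seed()`.
#' @export
shm_mutate <- function(seq, p, n = NULL) {
  stopifnot(p >= 0, p <= 1)
  codes <- aa_encode(if (is.null(n)) seq else rep(seq[1], n))
  out <- cpp_shm_mutate(codes, p)
  list(seqs = aa_decode(out$seqs), n_changes = out$n_changes)
}

#' Generate a founder B-cell pool by affinity filtering
#'
#' For each of the N antigens in the set, `pool_total / N` naive sequences
#' are generated by rejection sampling: uniform random sequences are kept
#' only if their affinity to the assigned antigen is at least
#' `min_affinity`.  Cross-reactivity to the other antigens is allowed and
#' untouched.  If `pool_total` is not divisible by N the quota is floored
#' and the remainder dropped with a warning.
#'
#' @param antigen_set an `antigen_set` (or a single `lattice_antigen`).
#' @param pool_total total pool size across antigens (default 1000).
#' @param min_affinity affinity floor against the assigned antigen
#'   (default 1e-4).
#' @param L BCR length (default 9).
#' @param U contact potential.
#' @param s stabilization factor.
#' @param min_contacts forwarded to [enumerate_poses()].
#' @param params affinity conversion parameters.
#' @param max_attempts sampling attempts allowed per antigen before failing
#'   with the best affinity seen (signals an unbindable antigen or a
#'   threshold mismatch).
#' @param inject optional character vector of sequences (memory-like
#'   founders) appended to the pool; they face the affinity floor against
#'   the first antigen unless `inject_filter = FALSE`.
#' @param inject_filter logical, see `inject`.
#' @return a `founder_pool`: data.frame `pool` (seq, antigen, energy,
#'   affinity) plus provenance.
#' @export
generate_founder_pool <- function(antigen_set, pool_total = 1000L,
                                  min_affinity = 1e-4, L = 9L,
                                  U = default_potential(), s = 1.0,
                                  min_contacts = 1L,
                                  params = affinity_params(),
                                  max_attempts = 1e7,
                                  inject = NULL, inject_filter = TRUE) {
  if (inherits(antigen_set, "lattice_antigen"))
    antigen_set <- build_antigen_set(list(antigen_set))
  stopifnot(inherits(antigen_set, "antigen_set"))
  N <- length(antigen_set$domains)
  quota <- pool_total %/% N
  if (quota * N != pool_total)
    warning("pool_total = ", pool_total, " is not divisible by ", N,
            " antigens; using ", quota, " founders per antigen (",
            pool_total - quota * N, " dropped)")
  if (params$mode != "strength")
    stop("founder filtering requires the strength-increasing affinity mode, ",
         "in which stronger binding (lower energy) means higher affinity")
  # higher affinity = lower energy: accept sequences with E <= thrE
  thrE <- if (min_affinity > 0) affinity_to_energy(min_affinity, params) else Inf
  rows <- vector("list", N)
  for (d in seq_len(N)) {
    ag <- antigen_set$domains[[d]]
    poses <- enumerate_poses(ag, L = L, min_contacts = min_contacts)
    if (min_affinity <= 0) {
      seqs <- random_bcr_panel(quota, L = L)
      be <- binding_energy(seqs, poses, U = U, s = s, params = params)
      rows[[d]] <- data.frame(seq = seqs, antigen = ag$id, energy = be$energy,
                              affinity = be$affinity, stringsAsFactors = FALSE)
    } else {
      smp <- cpp_sample_founders(poses$ptr, unclass(U), s, as.integer(quota),
                                 thrE, max_attempts)
      rows[[d]] <- data.frame(seq = aa_decode(smp$seqs), antigen = ag$id,
                              energy = smp$energy,
                              affinity = energy_to_affinity(smp$energy, params),
                              stringsAsFactors = FALSE)
    }
  }
  pool <- do.call(rbind, rows)
  if (!is.null(inject)) {
    ag <- antigen_set$domains[[1]]
    poses <- enumerate_poses(ag, L = L, min_contacts = min_contacts)
    be <- binding_energy(inject, poses, U = U, s = s, params = params)
    if (inject_filter && any(be$affinity < min_affinity))
      stop("injected founder(s) below the affinity floor: ",
           paste(inject[be$affinity < min_affinity], collapse = ", "))
    pool <- rbind(pool, data.frame(seq = inject, antigen = ag$id,
                                   energy = be$energy, affinity = be$affinity,
                                   stringsAsFactors = FALSE))
  }
  structure(list(pool = pool, min_affinity = min_affinity, L = L,
                 antigen_ids = vapply(antigen_set$domains, `[[`,
                                      character(1), "id")),
            class = "founder_pool")
}

#' @export
print.founder_pool <- function(x, ...) {
  cat("Founder pool:", nrow(x$pool), "sequences of length", x$L,
      "| affinity floor", x$min_affinity, "\n")
  print(table(x$pool$antigen))
  invisible(x)
}

#' Restrict a founder pool to a subset of antigens
#'
#' Used for single- or reduced-domain control immunizations: keeps only the
#' founders assigned to the named antigens.
#'
#' @param pool a `founder_pool`.
#' @param ids antigen identity labels to keep.
#' @return a `founder_pool`.
#' @export
founder_pool_subset <- function(pool, ids) {
  stopifnot(inherits(pool, "founder_pool"))
  missing_ids <- setdiff(ids, pool$antigen_ids)
  if (length(missing_ids) > 0)
    stop("pool has no founders for: ", paste(missing_ids, collapse = ", "))
  keep <- pool$pool$antigen %in% ids
  structure(list(pool = pool$pool[keep, , drop = FALSE],
                 min_affinity = pool$min_affinity, L = pool$L,
                 antigen_ids = ids),
            class = "founder_pool")
}

#' Write a founder pool (or any sequence table) to FASTA
#'
#' Record ids encode the antigen assignment:
#' `founder_<i>|antigen=<id>|affinity=<aff>`.
#'
#' @param pool a `founder_pool`.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_pool_fasta <- function(pool, file) {
  stopifnot(inherits(pool, "founder_pool"))
  ids <- sprintf("founder_%d|antigen=%s|affinity=%.6g",
                 seq_len(nrow(pool$pool)), pool$pool$antigen,
                 pool$pool$affinity)
  seqinr::write.fasta(as.list(pool$pool$seq), names = ids, file.out = file,
                      as.string = TRUE, nbchar = 80)
  invisible(file)
}

#' Read a founder pool from FASTA
#'
#' @param file FASTA written by [write_pool_fasta()].
#' @return a `founder_pool` (energies/affinities taken from headers where
#'   present, otherwise NA).
#' @export
read_pool_fasta <- function(file) {
  recs <- seqinr::read.fasta(file, as.string = TRUE, forceDNAtolower = FALSE)
  seqs <- toupper(vapply(recs, function(r) as.character(r)[1], character(1)))
  hdr <- names(recs)
  getfield <- function(h, key) {
    m <- regmatches(h, regexec(paste0(key, "=([^|]+)"), h))[[1]]
    if (length(m) == 2) m[2] else NA_character_
  }
  antigen <- vapply(hdr, getfield, character(1), key = "antigen",
                    USE.NAMES = FALSE)
  aff <- as.numeric(vapply(hdr, getfield, character(1), key = "affinity",
                           USE.NAMES = FALSE))
  structure(list(pool = data.frame(seq = unname(seqs), antigen = antigen,
                                   energy = NA_real_, affinity = aff,
                                   stringsAsFactors = FALSE),
                 min_affinity = NA_real_, L = nchar(seqs[1]),
                 antigen_ids = unique(antigen)),
            class = "founder_pool")
}
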