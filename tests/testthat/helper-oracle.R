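# Independent naive docking oracle, written directly from the model
# definition: enumerate every self-avoiding L-chain in a padded box around
# the antigen, keep those with at least min_contacts BCR-antigen
# adjacencies, and score sequences by re-walking each pose and summing
# adjacent residue pairs.  Deliberately free of the distance pruning,
# profile deduplication and bound-based early stopping used by the package
# engine (poses are kept as explicit coordinate lists).

oracle_dirs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                     c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))

# integer encoding of coordinates in [-50, 50]
oracle_enc <- function(p) (p[1] + 50) + 101 * (p[2] + 50) + 10201 * (p[3] + 50)

# all poses as a list of L x 3 position matrices, in (start, moves) order;
# node identity is tracked through the integer encoding of coordinates
oracle_enumerate <- function(antigen, L, min_contacts = 1) {
  agpos <- antigen$positions
  agocc <- logical(101^3)
  for (r in seq_len(nrow(agpos))) agocc[oracle_enc(agpos[r, ]) + 1] <- TRUE
  denc <- c(1L, -1L, 101L, -101L, 10201L, -10201L)
  lo <- apply(agpos, 2, min) - L - 1
  hi <- apply(agpos, 2, max) + L + 1
  occ <- logical(101^3)
  pos <- matrix(0L, nrow = L, ncol = 3)
  keys <- integer(L)
  poses <- list()
  recurse <- function(i, key) {
    if (i == L) {
      total <- 0L
      for (k in seq_len(L)) total <- total + sum(agocc[keys[k] + denc])
      if (total >= min_contacts) poses[[length(poses) + 1]] <<- pos + 0L
      return()
    }
    for (m in 1:6) {
      nk <- key + denc[m]
      if (agocc[nk] || occ[nk]) next
      pos[i + 1, ] <<- pos[i, ] + oracle_dirs[m, ]
      keys[i + 1] <<- nk
      occ[nk] <<- TRUE
      recurse(i + 1, nk)
      occ[nk] <<- FALSE
    }
  }
  for (x in lo[1]:hi[1]) for (y in lo[2]:hi[2]) for (z in lo[3]:hi[3]) {
    key <- oracle_enc(c(x, y, z)) + 1L
    if (agocc[key]) next
    pos[1, ] <- c(x, y, z)
    keys[1] <- key
    occ[key] <- TRUE
    recurse(1, key)
    occ[key] <- FALSE
  }
  poses
}

# energy of one pose for one sequence: sum U over BCR-antigen adjacencies
# plus s * U over non-covalent intra-BCR adjacencies
oracle_pose_energy <- function(pos, seq_res, antigen, U, s = 1.0) {
  agpos <- antigen$positions
  agkey <- paste(agpos[, 1], agpos[, 2], agpos[, 3])
  L <- nrow(pos)
  e <- 0
  for (i in seq_len(L)) {
    nb <- sweep(oracle_dirs, 2, pos[i, ], `+`)
    nbk <- paste(nb[, 1], nb[, 2], nb[, 3])
    hit <- match(nbk, agkey)
    for (h in hit[!is.na(hit)]) e <- e + U[seq_res[i], antigen$residues[h]]
    for (j in seq_len(L)) {
      if (j - i < 2) next
      if (any(nbk == paste(pos[j, 1], pos[j, 2], pos[j, 3])))
        e <- e + s * U[seq_res[i], seq_res[j]]
    }
  }
  e
}

# optimal energy for each sequence over a pre-enumerated pose list,
# vectorized over sequences within each pose
oracle_best_energy <- function(poses, seqs, antigen, U, s = 1.0) {
  agpos <- antigen$positions
  agkey <- paste(agpos[, 1], agpos[, 2], agpos[, 3])
  chars <- do.call(rbind, strsplit(seqs, ""))
  best <- rep(Inf, length(seqs))
  for (pos in poses) {
    L <- nrow(pos)
    e <- numeric(length(seqs))
    for (i in seq_len(L)) {
      nb <- sweep(oracle_dirs, 2, pos[i, ], `+`)
      nbk <- paste(nb[, 1], nb[, 2], nb[, 3])
      hit <- match(nbk, agkey)
      for (h in hit[!is.na(hit)])
        e <- e + U[cbind(chars[, i], antigen$residues[h])]
      for (j in seq_len(L)) {
        if (j - i < 2) next
        if (any(nbk == paste(pos[j, 1], pos[j, 2], pos[j, 3])))
          e <- e + s * U[cbind(chars[, i], chars[, j])]
      }
    }
    best <- pmin(best, e)
  }
  best
}
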