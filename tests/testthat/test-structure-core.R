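# Lattice geometry, chain validity, and the contact potential.

test_that("neighbors returns exactly the 6 unit offsets, symmetrically", {
  nb <- neighbors(c(0, 0, 0))
  expect_equal(nrow(nb), 6)
  expect_setequal(apply(nb, 1, paste, collapse = ","),
                  c("1,0,0", "-1,0,0", "0,1,0", "0,-1,0", "0,0,1", "0,0,-1"))
  set.seed(4)
  for (k in 1:20) {
    p <- sample(-5:5, 3, replace = TRUE)
    nb <- neighbors(p)
    expect_equal(nrow(nb), 6)
    for (r in seq_len(6)) {
      q <- nb[r, ]
      back <- neighbors(q)
      expect_true(any(back[, 1] == p[1] & back[, 2] == p[2] &
                        back[, 3] == p[3]))
    }
  }
})

test_that("validate_chain accepts straight chains, rejects revisits and diagonals", {
  straight <- cbind(0:4, 0L, 0L)
  expect_true(validate_chain(straight))
  revisit <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0), c(0, 0, 0))
  expect_false(validate_chain(revisit))
  diagonal <- rbind(c(0, 0, 0), c(1, 1, 0))
  expect_false(validate_chain(diagonal))
  expect_true(validate_chain(matrix(c(3, -2, 7), 1)))  # single residue
})

test_that("chain validity is invariant under the 24 lattice rotations", {
  set.seed(11)
  rots <- lattice_rotations()
  expect_length(rots, 24)
  chain <- generate_structure(12, compactness = 1)
  bad <- rbind(chain[1:5, ], chain[4, , drop = FALSE])  # revisit
  for (R in rots[c(1, 7, 13, 24)]) {
    shift <- sample(-3:3, 3, replace = TRUE)
    rchain <- sweep(chain %*% t(R), 2, shift, `+`)
    expect_true(validate_chain(rchain))
    rbad <- sweep(bad %*% t(R), 2, shift, `+`)
    expect_false(validate_chain(rbad))
  }
})

test_that("the packaged potential loads as a symmetric finite 20x20 matrix", {
  U <- load_potential()
  expect_equal(dim(U), c(20, 20))
  expect_true(all(is.finite(U)))
  expect_equal(unclass(U), t(unclass(U)), ignore_attr = TRUE)
  expect_setequal(rownames(U), latticeGC:::AA_ALPHABET)
})

test_that("contact_energy is commutative and matches the resource file", {
  U <- load_potential()
  expect_equal(contact_energy("A", "C", U), contact_energy("C", "A", U))
  expect_error(contact_energy("A", "B", U), "unknown residue")
  # oracle: re-read the resource file directly, independent of load_potential
  f <- system.file("extdata", "mj1996_contact_potential.txt",
                   package = "latticeGC")
  lines <- readLines(f)
  lines <- lines[!grepl("^\\s*#", lines)]
  hdr <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  row_w <- which(hdr == "W")
  col_f <- which(hdr == "F")
  raw <- as.numeric(strsplit(trimws(lines[1 + row_w]), "\\s+")[[1]])[col_f]
  expect_equal(contact_energy("W", "F", U), raw)
})

test_that("malformed potential files are rejected with informative messages", {
  f <- system.file("extdata", "mj1996_contact_potential.txt",
                   package = "latticeGC")
  lines <- readLines(f)
  body <- lines[!grepl("^\\s*#", lines)]
  # break symmetry in one entry
  asym <- body
  row2 <- as.numeric(strsplit(trimws(asym[3]), "\\s+")[[1]])
  row2[5] <- row2[5] + 1
  asym[3] <- paste(row2, collapse = " ")
  tf <- withr::local_tempfile(lines = asym, fileext = ".txt")
  expect_error(load_potential(tf), "not symmetric")
  # unknown residue letter in the header
  bad <- body
  bad[1] <- sub("W", "B", bad[1])
  tf2 <- withr::local_tempfile(lines = bad, fileext = ".txt")
  expect_error(load_potential(tf2), "unknown residue")
  # truncated table
  tf3 <- withr::local_tempfile(lines = body[1:10], fileext = ".txt")
  expect_error(load_potential(tf3), "malformed")
})

test_that("an all-zero potential is accepted and scores everything zero", {
  aa <- latticeGC:::AA_ALPHABET
  zero <- c(paste(aa, collapse = " "),
            replicate(20, paste(rep("0", 20), collapse = " ")))
  tf <- withr::local_tempfile(lines = zero, fileext = ".txt")
  U0 <- load_potential(tf)
  expect_true(all(U0 == 0))
  ag <- bent_pentamer()
  be <- binding_energy(c("AAAA", "WFYC"), ag, U = U0, L = 4)
  expect_equal(be$energy, c(0, 0))
  expect_equal(be$affinity, rep(energy_to_affinity(0), 2))
})

test_that("lattice structure files round-trip and reject malformed input", {
  ag <- bent_pentamer()
  tf <- withr::local_tempfile(fileext = ".txt")
  export_structure(ag, tf)
  back <- import_structure(tf, id = ag$id)
  expect_equal(back$positions, ag$positions)
  expect_equal(back$residues, ag$residues)
  # duplicate node: error names the line
  lines <- readLines(tf)
  dup <- c(lines, sub("^1 ", "6 ", lines[3]))
  tfd <- withr::local_tempfile(lines = dup, fileext = ".txt")
  expect_error(import_structure(tfd), "duplicate lattice node")
  # non-adjacent consecutive residues
  gap <- c("1 A 0 0 0", "2 C 2 0 0")
  tfg <- withr::local_tempfile(lines = gap, fileext = ".txt")
  expect_error(import_structure(tfg), "not lattice neighbors")
  # hand-written 4-residue file parses to the expected chain
  hand <- c("# comment", "1 F 0 0 0", "2 K 1 0 0", "3 W 1 1 0", "4 D 1 1 1")
  tfh_ <- withr::local_tempfile(lines = hand, fileext = ".txt")
  h <- import_structure(tfh_)
  expect_equal(h$residues, c("F", "K", "W", "D"))
  expect_equal(h$positions[4, ], c(1L, 1L, 1L))
})
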