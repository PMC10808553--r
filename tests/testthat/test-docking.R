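# Exhaustive docking engine vs the independent naive oracle, affinity
# conversion, and pose-set invariants.

test_that("pose counts match brute force for a single-residue antigen", {
  ag <- lattice_antigen(matrix(c(0L, 0L, 0L), 1), "W", id = "one")
  ps <- enumerate_poses(ag, L = 2, cache = FALSE)
  # brute force: ordered pairs of adjacent free nodes with >= 1 contact
  poses <- oracle_enumerate(ag, L = 2)
  expect_equal(ps$total_poses, length(poses))
  expect_equal(ps$total_poses, 60)
})

test_that("min_contacts beyond the geometric maximum yields an empty set", {
  ag <- bent_pentamer()
  ps <- enumerate_poses(ag, L = 3, min_contacts = 2 * 3 + 3, cache = FALSE)
  expect_equal(ps$n_profiles, 0)
  expect_equal(ps$total_poses, 0)
  expect_error(binding_energy("AAA", ps), "unbindable")
})

test_that("pose counts are invariant under lattice rotations of the antigen", {
  ag <- bent_pentamer()
  ps0 <- enumerate_poses(ag, L = 4, cache = FALSE)
  for (R in lattice_rotations()[c(3, 10, 17)]) {
    rag <- lattice_antigen(ag$positions %*% t(R) + 2L, ag$residues, id = "rot")
    psr <- enumerate_poses(rag, L = 4, cache = FALSE)
    expect_equal(psr$total_poses, ps0$total_poses)
    expect_equal(psr$n_profiles, ps0$n_profiles)
  }
})

test_that("optimal energies equal the naive enumerator exactly (toy oracle)", {
  set.seed(20)
  U <- default_potential()
  ag <- bent_pentamer()
  poses <- oracle_enumerate(ag, L = 4)
  ps <- enumerate_poses(ag, L = 4)
  seqs <- random_bcr_panel(120, L = 4)
  for (s in c(0, 1)) {
    ob <- oracle_best_energy(poses, seqs, ag, U, s = s)
    eb <- binding_energy(seqs, ps, U = U, s = s)$energy
    expect_equal(eb, ob, tolerance = 1e-12)
  }
})

test_that("profile energies match a geometric re-walk of the decoded pose", {
  set.seed(21)
  U <- default_potential()
  ag <- bent_pentamer()
  ps <- enumerate_poses(ag, L = 5)
  seqs <- random_bcr_panel(10, L = 5)
  be <- binding_energy(seqs, ps, U = U)
  profs <- pose_profiles(ps, be$profile)
  for (k in seq_along(seqs)) {
    # independent energy: decode the representative pose and re-walk it
    pos <- pose_positions(profs[[k]])
    expect_true(validate_chain(pos))
    res <- strsplit(seqs[k], "")[[1]]
    e_walk <- oracle_pose_energy(pos, res, ag, U, s = 1)
    expect_equal(be$energy[k], e_walk, tolerance = 1e-12)
    # and through profile_energy on the decoded contact lists
    expect_equal(profile_energy(seqs[k], profs[[k]], U = U, s = 1),
                 be$energy[k], tolerance = 1e-12)
  }
})

test_that("profiles with no intra contacts are independent of s", {
  ag <- lattice_antigen(matrix(c(0L, 0L, 0L), 1), "C", id = "one")
  ps <- enumerate_poses(ag, L = 2, cache = FALSE)
  be1 <- binding_energy("FW", ps, s = 0)
  be2 <- binding_energy("FW", ps, s = 7)
  expect_equal(be1$energy, be2$energy)
})

test_that("scaling the potential scales optimal energies, preserving the pose", {
  set.seed(22)
  U <- default_potential()
  ag <- bent_pentamer()
  ps <- enumerate_poses(ag, L = 4)
  seqs <- random_bcr_panel(25, L = 4)
  b1 <- binding_energy(seqs, ps, U = U, s = 0)
  U3 <- unclass(U) * 3
  class(U3) <- class(U)
  b3 <- binding_energy(seqs, ps, U = U3, s = 0)
  expect_equal(b3$energy, 3 * b1$energy, tolerance = 1e-12)
  expect_equal(b3$pose_id, b1$pose_id)
})

test_that("energy ordering is the reverse of affinity ordering", {
  set.seed(23)
  ag <- bent_pentamer()
  be <- binding_energy(random_bcr_panel(50, L = 4), ag, L = 4)
  expect_equal(order(be$energy), order(-be$affinity))
})

test_that("affinity conversion matches the closed form and inverts exactly", {
  expect_equal(energy_to_affinity(-100), 1.0)
  expect_equal(energy_to_affinity(-74.2), exp((-100 + 74.2) / 2.8))
  expect_equal(energy_to_affinity(-74.2), 9.95e-5, tolerance = 1e-3)
  # stronger binding than the reference exceeds affinity 1
  expect_equal(energy_to_affinity(-110), exp(10 / 2.8))
  expect_gt(energy_to_affinity(-110), 1)
  # inverse map
  expect_equal(affinity_to_energy(1.0), -100)
  expect_equal(affinity_to_energy(1e-8), -100 + 2.8 * log(1e8))
  for (E in c(-120, -100, -74.2, -50, 0)) {
    expect_equal(affinity_to_energy(energy_to_affinity(E)), E,
                 tolerance = 1e-12)
    lit <- affinity_params(mode = "literal")
    expect_equal(affinity_to_energy(energy_to_affinity(E, lit), lit), E,
                 tolerance = 1e-12)
  }
  expect_error(affinity_to_energy(0), "positive")
  expect_error(affinity_params(C = -1), "positive")
  # literal mode implements the opposite sign
  expect_equal(energy_to_affinity(-90, affinity_params(mode = "literal")),
               exp(10 / 2.8))
})

test_that("scoring through a cached pose set equals independent enumerations", {
  set.seed(24)
  U <- default_potential()
  ag <- bent_pentamer()
  seqs <- random_bcr_panel(40, L = 4)
  cached <- enumerate_poses(ag, L = 4)          # session cache
  b_cached <- binding_energy(seqs, cached, U = U)
  fresh <- enumerate_poses(ag, L = 4, cache = FALSE)
  b_fresh <- binding_energy(seqs, fresh, U = U)
  expect_equal(b_cached$energy, b_fresh$energy)
  expect_equal(b_cached$pose_id, b_fresh$pose_id)
})

test_that("energies are invariant under joint rotation of the antigen", {
  set.seed(25)
  U <- default_potential()
  ag <- bent_pentamer()
  seqs <- random_bcr_panel(30, L = 4)
  e0 <- binding_energy(seqs, enumerate_poses(ag, L = 4), U = U)$energy
  R <- lattice_rotations()[[9]]
  rag <- lattice_antigen(ag$positions %*% t(R) - 1L, ag$residues, id = "r9")
  er <- binding_energy(seqs, enumerate_poses(rag, L = 4, cache = FALSE),
                       U = U)$energy
  expect_equal(er, e0, tolerance = 1e-12)
})

test_that("empty antigens and bad lengths are rejected", {
  ag <- bent_pentamer()
  ps <- enumerate_poses(ag, L = 4)
  expect_error(binding_energy("AAAAA", ps), "does not match")
  expect_error(enumerate_poses(ag, L = 1), "at least 2")
  expect_error(enumerate_poses(ag, L = 4, min_contacts = 0), "min_contacts")
})
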