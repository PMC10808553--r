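# Synthetic antigen generation, immunogenicity classification, and dosing.

test_that("generate_structure is seeded, valid, and respects length", {
  set.seed(31)
  a <- generate_structure(20, compactness = 0)
  set.seed(31)
  b <- generate_structure(20, compactness = 0)
  expect_identical(a, b)
  expect_true(validate_chain(a))
  expect_equal(nrow(a), 20)
  expect_true(validate_chain(generate_structure(4)))
})

test_that("compactness biases walks toward smaller extent", {
  # Monte Carlo: mean squared end-to-end distance of biased walks is well
  # below that of uniform growth walks, and grows with n for uniform walks
  set.seed(32)
  r2 <- function(n, comp, reps = 120) {
    mean(replicate(reps, {
      p <- generate_structure(n, compactness = comp)
      sum((p[n, ] - p[1, ])^2)
    }))
  }
  expect_lt(r2(24, 8), r2(24, 0))
  expect_lt(r2(10, 0), r2(28, 0))
})

test_that("randomize_residues keeps geometry and draws uniformly", {
  set.seed(33)
  pos <- generate_structure(10, compactness = 2)
  ag1 <- randomize_residues(pos, id = "x")
  expect_equal(ag1$positions, matrix(as.integer(pos), ncol = 3))
  set.seed(99)
  a <- randomize_residues(pos)$residues
  set.seed(99)
  b <- randomize_residues(pos)$residues
  expect_identical(a, b)
  # uniformity: chi-square over many assignments must not reject at 1%
  set.seed(34)
  draws <- unlist(replicate(1000, randomize_residues(pos)$residues,
                            simplify = FALSE))
  tab <- table(factor(draws, levels = latticeGC:::AA_ALPHABET))
  p <- chisq.test(tab)$p.value
  expect_gt(p, 0.01)
})

test_that("average_panel_energy is the arithmetic mean of oracle energies", {
  set.seed(35)
  U <- default_potential()
  ag <- bent_pentamer()
  panel <- random_bcr_panel(10, L = 4)
  poses <- oracle_enumerate(ag, L = 4)
  oracle_mean <- mean(oracle_best_energy(poses, panel, ag, U))
  expect_equal(average_panel_energy(ag, panel, U = U), oracle_mean,
               tolerance = 1e-12)
  # single-sequence panel equals that sequence's energy
  expect_equal(average_panel_energy(ag, panel[3], U = U),
               binding_energy(panel[3], ag, L = 4, U = U)$energy)
  expect_error(average_panel_energy(ag, character(0)), "non-empty")
})

test_that("immunogenicity classes partition the energy axis as specified", {
  expect_equal(classify_immunogenicity(-76), "A")
  expect_equal(classify_immunogenicity(-59), "H")
  expect_equal(classify_immunogenicity(-68), "D")
  # boundaries belong to the right (less immunogenic) class
  expect_equal(classify_immunogenicity(-75), "B")
  expect_equal(classify_immunogenicity(-60), "H")
  expect_equal(classify_immunogenicity(-62.5), "G")
  # every finite value maps to exactly one of the eight labels
  grid <- seq(-100, -40, by = 0.31)
  lab <- classify_immunogenicity(grid)
  expect_true(all(lab %in% LETTERS[1:8]))
  expect_equal(length(lab), length(grid))
  # monotone: less negative energy never yields a more immunogenic class
  expect_true(all(diff(match(lab, LETTERS)) >= 0))
  expect_error(classify_immunogenicity(NaN), "finite")
})

test_that("antigen sets divide the dose equally", {
  ags <- lapply(1:5, function(i)
    lattice_antigen(cbind(0:3, 0L, 0L), c("A", "C", "D", "E"),
                    id = paste0("D", i)))
  expect_equal(build_antigen_set(ags[1:2], 3000)$per_domain_dose, 1500)
  expect_equal(build_antigen_set(ags[1], 3000)$per_domain_dose, 3000)
  expect_equal(build_antigen_set(ags, 3000)$per_domain_dose, 600)
  expect_error(build_antigen_set(list(), 3000), "at least one")
  expect_error(build_antigen_set(ags[c(1, 1)], 3000), "unique")
})

test_that("antigen_library screens compositions into classes on one geometry", {
  set.seed(36)
  pos <- generate_structure(8, compactness = 2)
  panel <- random_bcr_panel(25, L = 4)
  lib <- antigen_library(pos, count = 12, panel = panel, L = 4)
  expect_equal(nrow(lib$table), 12)
  expect_true(all(lib$table$class %in% LETTERS[1:8]))
  # classification consistent with the recorded means
  expect_equal(classify_immunogenicity(lib$table$mean_energy),
               lib$table$class)
  # recomputing one variant's panel mean reproduces the table entry
  k <- which.min(lib$table$mean_energy)
  expect_equal(average_panel_energy(lib$antigens[[k]], panel),
               lib$table$mean_energy[k], tolerance = 1e-12)
})
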