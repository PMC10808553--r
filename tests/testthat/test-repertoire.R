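# Naive panels, the SHM operator, and founder-pool construction.

test_that("random panels are seeded and near-uniform per position", {
  set.seed(41)
  a <- random_bcr_panel(200, L = 9)
  set.seed(41)
  b <- random_bcr_panel(200, L = 9)
  expect_identical(a, b)
  expect_equal(length(a), 200)
  expect_true(all(nchar(a) == 9))
  expect_equal(length(random_bcr_panel(1, L = 9)), 1)
  set.seed(42)
  big <- random_bcr_panel(11000, L = 9)
  chars <- unlist(strsplit(big, ""))
  p <- chisq.test(table(factor(chars, levels = latticeGC:::AA_ALPHABET)))$p.value
  expect_gt(p, 0.01)
})

test_that("SHM replaces residues with guaranteed changes at rate p", {
  s <- "ACDEFGHIK"
  set.seed(43)
  m0 <- shm_mutate(s, p = 0)
  expect_equal(m0$seqs, s)
  expect_equal(m0$n_changes, 0L)
  m1 <- shm_mutate(s, p = 1)
  expect_equal(m1$n_changes, 9L)
  expect_true(all(strsplit(m1$seqs, "")[[1]] != strsplit(s, "")[[1]]))
  expect_true(all(nchar(shm_mutate(s, 0.5, n = 50)$seqs) == 9))
})

test_that("replacement counts are Binomial(L, p)", {
  set.seed(44)
  n <- 1e5
  res <- shm_mutate("ACDEFGHIK", p = 0.055, n = n)
  tab <- table(factor(res$n_changes, levels = 0:9))
  expected <- dbinom(0:9, 9, 0.055) * n
  keep <- expected > 5
  chi <- sum((as.numeric(tab[keep]) - expected[keep])^2 / expected[keep])
  p <- pchisq(chi, df = sum(keep) - 1, lower.tail = FALSE)
  expect_gt(p, 0.01)
  # the printed arithmetic: 9 x 0.055 = 0.495, i.e. ~0.5 per division
  expect_equal(mean(res$n_changes), 0.495, tolerance = 0.05)
})

test_that("founder pools meet quotas and the affinity floor by construction", {
  fx <- get_fixtures()
  pool <- fx$pool
  expect_s3_class(pool, "founder_pool")
  expect_equal(nrow(pool$pool), 200)
  expect_equal(unname(table(pool$pool$antigen)["hi"]), 100)
  expect_equal(unname(table(pool$pool$antigen)["lo"]), 100)
  # post-hoc re-verification of the floor against the assigned antigen
  for (id in c("hi", "lo")) {
    ag <- fx[[id]]
    sel <- pool$pool$antigen == id
    be <- binding_energy(pool$pool$seq[sel], ag, L = 5, params = toy_params())
    expect_true(all(be$affinity >= pool$min_affinity))
    expect_equal(be$affinity, pool$pool$affinity[sel], tolerance = 1e-9)
  }
})

test_that("a zero affinity floor accepts the first draws unchanged", {
  ag <- bent_pentamer()
  set.seed(45)
  pool <- generate_founder_pool(ag, pool_total = 30, min_affinity = 0, L = 4)
  set.seed(45)
  direct <- random_bcr_panel(30, L = 4)
  expect_equal(pool$pool$seq, direct)
})

test_that("non-divisible pool totals floor the quota with a warning", {
  fx <- get_fixtures()
  aset <- build_antigen_set(list(fx$hi, fx$lo))
  set.seed(46)
  expect_warning(
    pool <- generate_founder_pool(aset, pool_total = 25, min_affinity = 0,
                                  L = 5),
    "not divisible")
  expect_equal(nrow(pool$pool), 24)
})

test_that("unreachable thresholds fail with the best affinity seen", {
  ag <- bent_pentamer()
  set.seed(47)
  expect_error(
    generate_founder_pool(ag, pool_total = 10, min_affinity = 1e-4, L = 4,
                          max_attempts = 2000),
    "acceptance too low")
})

test_that("injected memory-like founders face the affinity floor", {
  fx <- get_fixtures()
  aset <- build_antigen_set(list(fx$hi))
  set.seed(48)
  good <- founder_pool_subset(fx$pool, "hi")$pool$seq[1:3]
  pool <- generate_founder_pool(aset, pool_total = 10, min_affinity = 1e-3,
                                L = 5, params = toy_params(), inject = good)
  expect_equal(nrow(pool$pool), 13)
  set.seed(48)
  expect_error(
    generate_founder_pool(aset, pool_total = 10, min_affinity = 0.99,
                          L = 5, params = toy_params(), inject = good,
                          max_attempts = 1),
    "below the affinity floor|acceptance too low")
})

test_that("founder pools round-trip through FASTA", {
  fx <- get_fixtures()
  tf <- withr::local_tempfile(fileext = ".fasta")
  write_pool_fasta(fx$pool, tf)
  back <- read_pool_fasta(tf)
  expect_equal(back$pool$seq, fx$pool$pool$seq)
  expect_equal(back$pool$antigen, fx$pool$pool$antigen)
  expect_equal(back$pool$affinity, fx$pool$pool$affinity, tolerance = 1e-4)
})
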