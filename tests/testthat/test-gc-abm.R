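# The agent-based GC simulation: configuration, initialization, influx,
# division map, determinism, conservation and state-machine behavior.

test_that("configuration validates keys, ranges and the capture cadence", {
  cfg <- gc_config()
  expect_equal(cfg$cycle_mean, 7.5)
  expect_equal(cfg$shm_p, 0.055)
  expect_equal(cfg$antigen_total, 3000)
  expect_equal(cfg$n_tfh, 250L)
  expect_error(gc_config(cycle_mean = -1), "positive")
  expect_error(gc_config(no_such_key = 1), "unknown configuration key")
  expect_error(gc_config(dt = 0.0003), "divide")
  expect_error(gc_config(asym_prob = 1.2), "0, 1")
})

test_that("configuration files load with defaults, overrides and rejections", {
  empty <- withr::local_tempfile(lines = character(0), fileext = ".yaml")
  cfg <- load_config(empty)
  expect_equal(unclass(cfg), unclass(gc_config()))
  half <- withr::local_tempfile(lines = "antigen_total: 1500",
                                fileext = ".yaml")
  expect_equal(load_config(half)$antigen_total, 1500)
  bad <- withr::local_tempfile(lines = "antigen_totl: 1500",
                               fileext = ".yaml")
  expect_error(load_config(bad), "antigen_totl")
  # round trip
  tf <- withr::local_tempfile(fileext = ".yaml")
  write_config(gc_config(seed = 9, sim_days = 3), tf)
  expect_equal(load_config(tf)$seed, 9)
})

test_that("initialization places the published agent counts and doses", {
  fx <- get_fixtures()
  # full-size geometry with the published counts; antigen on FDCs sums to
  # the total dose, halved per domain for two domains
  cfg <- gc_config(bcr_length = 5L, seed = 5)
  ini2 <- gc_initialize(cfg, build_antigen_set(list(fx$hi, fx$lo)), fx$pool)
  expect_equal(ini2$state$n_tfh, 250)
  expect_equal(ini2$state$n_stromal, 300)
  expect_equal(ini2$state$antigen_on_fdc, 3000)
  expect_equal(unname(ini2$antigen_per_domain), c(1500, 1500))
  expect_equal(ini2$state$n_bcells, 0)
  ini1 <- gc_initialize(cfg, build_antigen_set(list(fx$hi)),
                        founder_pool_subset(fx$pool, "hi"))
  expect_equal(unname(ini1$antigen_per_domain), 3000)
})

test_that("founder influx is Poisson with the configured rate", {
  fx <- get_fixtures()
  aset <- build_antigen_set(list(fx$hi))
  pool <- founder_pool_subset(fx$pool, "hi")
  # 10 simulated hours at 2 cells/h; founders counted on arrival
  counts <- vapply(1:120, function(i) {
    cfg <- gc_toy_config(seed = 1000 + i, sim_days = 10 / 24,
                         founder_divisions = 6L)
    gc_run(cfg, aset, pool)$state$founders_arrived
  }, numeric(1))
  lambda <- 2 * 10
  se <- sqrt(lambda / length(counts))
  expect_lt(abs(mean(counts) - lambda), 3 * se)
  expect_gt(var(counts), lambda * 0.5)  # dispersion consistent with Poisson
})

test_that("the division map is a bounded monotone Hill function", {
  expect_equal(divisions_from_antigen(0), 1)
  expect_equal(divisions_from_antigen(0, nmax = 6), 1)
  expect_equal(divisions_from_antigen(1e6), 6)
  a <- 0:50
  d <- divisions_from_antigen(a)
  expect_true(all(diff(d) >= 0))
  expect_true(all(d >= 1 & d <= 6))
  d2 <- divisions_from_antigen(a, K = 2, h = 2)
  expect_true(all(diff(d2) >= 0))
  expect_equal(divisions_from_antigen(2, K = 2, h = 2), 4)  # midpoint rounds up
})

test_that("cell-cycle draws are truncated-normal around the configured mean", {
  x <- draw_cycle_times(2e4, mean = 7.5, sd = 1.25, seed = 7)
  expect_true(all(x > 0))
  expect_lt(abs(mean(x) - 7.5), 3 * 1.25 / sqrt(2e4))
  expect_lt(abs(sd(x) - 1.25), 0.05)
  # reproducible for a fixed seed
  expect_identical(x, draw_cycle_times(2e4, 7.5, 1.25, seed = 7))
})

test_that("runs are deterministic given the seed and differ across seeds", {
  fx <- get_fixtures()
  aset <- build_antigen_set(list(fx$hi))
  pool <- founder_pool_subset(fx$pool, "hi")
  cfg <- gc_toy_config(seed = 77, sim_days = 2)
  s1 <- gc_run(cfg, aset, pool)
  s2 <- gc_run(cfg, aset, pool)
  expect_identical(s1$metrics, s2$metrics)
  expect_identical(s1$outputs, s2$outputs)
  s3 <- gc_run(gc_toy_config(seed = 78, sim_days = 2), aset, pool)
  expect_false(identical(s1$metrics$n_bcells, s3$metrics$n_bcells))
})

test_that("a GC without antigen collapses: all searchers die unselected", {
  fx <- get_fixtures()
  aset <- build_antigen_set(list(fx$hi), total_dose = 1e-9)
  pool <- founder_pool_subset(fx$pool, "hi")
  cfg <- gc_toy_config(seed = 5, sim_days = 4, inflow_duration = 24)
  sim <- gc_run(cfg, aset, pool)
  expect_equal(sim$state$antigen_total, 0)
  expect_equal(nrow(sim$outputs), 0)       # no capture, no output
  expect_equal(sim$state$n_bcells, 0)      # everyone dies after searching
  expect_gt(sim$state$apoptosis_count, 0)
})

test_that("a prohibitive capture floor prevents all captures", {
  fx <- get_fixtures()
  aset <- build_antigen_set(list(fx$hi))
  pool <- founder_pool_subset(fx$pool, "hi")
  cfg <- gc_toy_config(seed = 6, sim_days = 4, inflow_duration = 24,
                       capture_min_affinity = 1e9)
  sim <- gc_run(cfg, aset, pool)
  expect_equal(sim$state$antigen_on_fdc, sim$state$antigen_total)
  expect_equal(nrow(sim$outputs), 0)
})

test_that("state tables expose only documented states and sane clocks", {
  fx <- get_fixtures()
  cfg <- gc_toy_config(seed = 8, sim_days = 3)
  sim <- gc_run(cfg, build_antigen_set(list(fx$hi)),
                founder_pool_subset(fx$pool, "hi"),
                cell_snapshot_times = c(24, 60))
  for (snap in sim$snapshots) {
    expect_true(all(snap$state %in%
                      c("centroblast", "unselected_cc", "contacting_tfh")))
    expect_true(all(snap$antigen >= 0))
    expect_true(all(snap$mutations >= 0))
  }
  # outputs are cumulative and never decrease
  expect_true(all(diff(sim$metrics$outputs_cum) >= 0))
  # diversity never exceeds the population
  ok <- sim$metrics$n_bcells > 0
  expect_true(all(sim$metrics$diversity[ok] <= sim$metrics$n_bcells[ok]))
})

test_that("the antigen ledger balances exactly at every step of a toy run", {
  fx <- get_fixtures()
  cfg <- gc_toy_config(seed = 9, sim_days = 4, audit_every_step = TRUE)
  sim <- gc_run(cfg, build_antigen_set(list(fx$hi, fx$lo)), fx$pool)
  expect_equal(sim$state$ledger_violations, 0)
  expect_equal(sim$state$occupancy_violations, 0)
  m <- sim$metrics
  expect_true(all(m$antigen_on_fdc + m$antigen_in_cells + m$antigen_removed ==
                    sim$state$antigen_total))
})

test_that("halving dt leaves toy summary trajectories statistically alike", {
  fx <- get_fixtures()
  aset <- build_antigen_set(list(fx$hi))
  pool <- founder_pool_subset(fx$pool, "hi")
  pops <- sapply(c(0.01, 0.005), function(step) {
    vapply(1:4, function(i) {
      cfg <- gc_toy_config(seed = 300 + i, sim_days = 3, dt = step,
                           capture_check_interval = 0.01)
      max(gc_run(cfg, aset, pool)$metrics$n_bcells)
    }, numeric(1))
  })
  # peak populations overlap within 3 pooled standard errors
  se <- sqrt(var(pops[, 1]) / 4 + var(pops[, 2]) / 4)
  expect_lt(abs(mean(pops[, 1]) - mean(pops[, 2])), 3 * se + 1e-9)
})

test_that("run artifacts and the manifest are written and reproducible", {
  fx <- get_fixtures()
  aset <- build_antigen_set(list(fx$hi))
  pool <- founder_pool_subset(fx$pool, "hi")
  cfg <- gc_toy_config(seed = 12, sim_days = 2)
  sim <- gc_run(cfg, aset, pool)
  dir <- withr::local_tempdir()
  man <- write_gc_run(sim, dir, antigen_set = aset, founder_pool = pool)
  expect_true(all(file.exists(file.path(dir, c(
    "timeseries.csv", "ledger.csv", "outputs.fasta", "summary.json",
    "manifest.json")))))
  ts <- read.csv(file.path(dir, "timeseries.csv"))
  expect_equal(nrow(ts), nrow(sim$metrics))
  # the manifest pins config, seed and input hashes
  expect_equal(man$seed, 12)
  expect_equal(man$antigen_hashes[[1]], antigen_hash(fx$hi))
  # identical rerun produces identical artifacts
  sim2 <- gc_run(cfg, aset, pool)
  dir2 <- withr::local_tempdir()
  write_gc_run(sim2, dir2, antigen_set = aset, founder_pool = pool)
  expect_identical(readLines(file.path(dir, "timeseries.csv")),
                   readLines(file.path(dir2, "timeseries.csv")))
  expect_identical(readLines(file.path(dir, "outputs.fasta")),
                   readLines(file.path(dir2, "outputs.fasta")))
})
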