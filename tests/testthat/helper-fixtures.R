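# Shared, lazily built fixtures.  Everything is generated in code from fixed
# seeds; heavier objects are memoized so that test files can share them
# within one session.

.fx_env <- new.env()

get_fixtures <- function() {
  if (is.null(.fx_env$fx)) .fx_env$fx <- make_fixtures(1)
  .fx_env$fx
}

toy_params <- function() affinity_params(Emax = -50)

# a tiny fixed antigen usable without RNG
bent_pentamer <- function() {
  lattice_antigen(rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0),
                        c(0, 1, 1)),
                  c("F", "K", "W", "D", "R"), id = "bent5")
}

# memoized replicate batches for the trend checks (5 seeded replicates each)
trend_reps <- function(tag, antigens, pool, n = 5, ...) {
  key <- paste0("trend_", tag)
  if (is.null(.fx_env[[key]])) {
    cfg <- gc_toy_config(seed = 101, ...)
    .fx_env[[key]] <- gc_run_replicates(cfg, antigens, pool, n = n,
                                        keep_runs = TRUE)
  }
  .fx_env[[key]]
}

hi_alone_reps <- function() {
  fx <- get_fixtures()
  trend_reps("hi", build_antigen_set(list(fx$hi)),
             founder_pool_subset(fx$pool, "hi"))
}

lo_alone_reps <- function() {
  fx <- get_fixtures()
  trend_reps("lo", build_antigen_set(list(fx$lo)),
             founder_pool_subset(fx$pool, "lo"))
}

hilo_reps <- function() {
  fx <- get_fixtures()
  trend_reps("hilo", build_antigen_set(list(fx$hi, fx$lo)), fx$pool)
}
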