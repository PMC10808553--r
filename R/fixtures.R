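# Standard synthetic test bundle: small antigens of controlled relative
# immunogenicity obtained by composition screening (the same screening route
# used to build antigen libraries), plus a naive panel and a founder pool.
# Everything is generated from the seed; no stored data.

#' Generate the standard synthetic fixture bundle
#'
#' Produces, reproducibly from `seed`:
#' * `tiny`: a 6-residue antigen (brute-force-checkable docking scale);
#' * `small`: a 20-residue antigen;
#' * `hi`, `lo`: a pair of antigens sharing one compact structure whose mean
#'   panel energies differ by at least `gap_kT` (hi = more immunogenic, i.e.
#'   lower mean energy), found by screening random residue assignments;
#' * `lo_extra`: additional low-immunogenicity variants with mean energy
#'   close to `lo`'s, for valency experiments;
#' * `panel`: a naive BCR panel of `panel_n` sequences;
#' * `pool`: a founder pool for the `hi`+`lo` pair at `min_affinity`;
#' * `screen`: the screening table (id, mean energy, class).
#'
#' @param seed integer seed.
#' @param L BCR length used for screening and the pool (default 5, the
#'   reduced scale used throughout the test suite).
#' @param n_res size of the shared hi/lo structure (default 10).
#' @param gap_kT required gap between hi and lo mean panel energies.
#' @param n_lo_extra number of additional lo-like variants.
#' @param screen_batch antigens screened per batch until the gap is met.
#' @param panel_n naive panel size.
#' @param pool_total,min_affinity founder pool parameters (defaults match
#'   the reduced-scale configuration preset).
#' @param params affinity conversion parameters for the founder pool; the
#'   default matches the reduced-scale preset of [gc_toy_config()].
#' @param compactness growth bias of the shared structure.
#' @return a named list with the components above.
#' @export
make_fixtures <- function(seed, L = 5L, n_res = 10L, gap_kT = 5,
                          n_lo_extra = 2L, screen_batch = 40L, panel_n = 200L,
                          pool_total = 200L, min_affinity = 1e-3,
                          params = affinity_params(Emax = -50),
                          compactness = 2) {
  set.seed(seed)
  tiny <- randomize_residues(generate_structure(6, compactness = 1),
                             id = "tiny")
  small <- randomize_residues(generate_structure(20, compactness = 2),
                              id = "small")
  shared <- generate_structure(n_res, compactness = compactness)
  panel <- random_bcr_panel(panel_n, L = L)
  screen_panel <- panel[seq_len(min(50, panel_n))]

  antigens <- list()
  tab <- NULL
  for (batch in 1:5) {
    lib <- antigen_library(shared, count = screen_batch, panel = screen_panel,
                           L = L, id_prefix = sprintf("v%d_", batch))
    antigens <- c(antigens, lib$antigens)
    tab <- rbind(tab, lib$table)
    if (diff(range(tab$mean_energy)) >= gap_kT) break
  }
  if (diff(range(tab$mean_energy)) < gap_kT)
    stop("screening failed to produce a ", gap_kT,
         " kT immunogenicity gap after ", nrow(tab), " antigens")

  hi_i <- which.min(tab$mean_energy)
  hiE <- tab$mean_energy[hi_i]
  # lo: among variants at least gap_kT above hi, the one closest to the gap
  cand <- which(tab$mean_energy >= hiE + gap_kT)
  lo_i <- cand[which.min(tab$mean_energy[cand] - (hiE + gap_kT))]
  # extra lo-like variants: closest mean energies to lo's, excluding hi/lo
  rest <- setdiff(seq_len(nrow(tab)), c(hi_i, lo_i))
  extra_i <- rest[order(abs(tab$mean_energy[rest] - tab$mean_energy[lo_i]))]
  extra_i <- head(extra_i, n_lo_extra)

  relabel <- function(i, id) {
    ag <- antigens[[i]]
    ag$id <- id
    ag
  }
  hi <- relabel(hi_i, "hi")
  lo <- relabel(lo_i, "lo")
  lo_extra <- lapply(seq_along(extra_i), function(k)
    relabel(extra_i[k], paste0("lo", k + 1)))

  pool <- generate_founder_pool(build_antigen_set(list(hi, lo)),
                                pool_total = pool_total,
                                min_affinity = min_affinity, L = L,
                                params = params)
  list(tiny = tiny, small = small, hi = hi, lo = lo, lo_extra = lo_extra,
       panel = panel, pool = pool, screen = tab,
       mean_energy = c(hi = tab$mean_energy[hi_i],
                       lo = tab$mean_energy[lo_i],
                       setNames(tab$mean_energy[extra_i],
                                paste0("lo", seq_along(extra_i) + 1))))
}
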