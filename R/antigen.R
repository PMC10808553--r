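# Synthetic lattice antigens.  Structures are self-avoiding walks on the
# cubic lattice with an optional compactness bias; residues are assigned
# uniformly at random.  Immunogenicity is operationalized as the mean optimal
# binding energy of the antigen against a panel of random naive BCR
# sequences, binned into classes A (most immunogenic, mean energy < -75 kT)
# through H (least immunogenic, mean energy >= -60 kT) in 2.5-kT steps.

#' Construct a lattice antigen
#'
#' @param positions integer matrix (n x 3) of lattice coordinates; must be a
#'   valid self-avoiding connected chain.
#' @param residues character vector of residue letters, one per position.
#' @param id identity label.
#' @param class_label immunogenicity class, `NA` if unassigned.
#' @return a `lattice_antigen` object.
#' @export
lattice_antigen <- function(positions, residues, id = "antigen",
                            class_label = NA_character_) {
  positions <- matrix(as.integer(positions), ncol = 3)
  if (!validate_chain(positions))
    stop("positions do not form a valid self-avoiding lattice chain")
  residues <- as.character(residues)
  if (length(residues) != nrow(positions))
    stop("residues and positions lengths differ")
  if (!all(residues %in% AA_ALPHABET))
    stop("unknown residue letter: ",
         paste(setdiff(residues, AA_ALPHABET), collapse = ", "))
  structure(list(positions = positions, residues = residues, id = id,
                 class_label = class_label),
            class = "lattice_antigen")
}

#' @export
print.lattice_antigen <- function(x, ...) {
  cat("Lattice antigen '", x$id, "': ", nrow(x$positions), " residues",
      if (!is.na(x$class_label)) paste0(", class ", x$class_label), "\n",
      sep = "")
  invisible(x)
}

#' Generate a random lattice structure
#'
#' Grows a self-avoiding walk on the cubic lattice.  At each step the next
#' node is drawn among the free neighbors with weight
#' `1 + compactness * (number of chain nodes already adjacent to the
#' candidate)`, so `compactness = 0` gives a uniform self-avoiding growth
#' walk and larger values produce globular structures.  Dead ends trigger a
#' restart; reproducible under `set.seed()`.
#'
#' @param n_residues chain length (>= 4).
#' @param compactness nonnegative weight biasing growth toward the existing
#'   chain (default 0).
#' @param max_restarts restarts allowed before giving up.
#' @return an n x 3 integer matrix of positions (a valid chain).
#' @export
generate_structure <- function(n_residues, compactness = 0,
                               max_restarts = 1000L) {
  stopifnot(n_residues >= 4, compactness >= 0)
  offs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  for (attempt in seq_len(max_restarts)) {
    pos <- matrix(0L, nrow = n_residues, ncol = 3)
    occ <- new.env(parent = emptyenv(), size = 2L * n_residues)
    assign("0 0 0", TRUE, envir = occ)
    ok <- TRUE
    for (i in 2:n_residues) {
      cand <- sweep(offs, 2, pos[i - 1, ], `+`)
      keys <- paste(cand[, 1], cand[, 2], cand[, 3])
      free <- !vapply(keys, exists, logical(1), envir = occ, USE.NAMES = FALSE)
      if (!any(free)) { ok <- FALSE; break }
      cand <- cand[free, , drop = FALSE]
      keys <- keys[free]
      w <- rep(1, nrow(cand))
      if (compactness > 0) {
        for (k in seq_len(nrow(cand))) {
          nb <- sweep(offs, 2, cand[k, ], `+`)
          nbk <- paste(nb[, 1], nb[, 2], nb[, 3])
          adj <- sum(vapply(nbk, exists, logical(1), envir = occ,
                            USE.NAMES = FALSE))
          w[k] <- 1 + compactness * adj
        }
      }
      pick <- sample.int(nrow(cand), 1, prob = w)
      pos[i, ] <- cand[pick, ]
      assign(keys[pick], TRUE, envir = occ)
    }
    if (ok) return(pos)
  }
  stop("self-avoiding walk dead-ended after ", max_restarts, " restarts")
}

#' Assign uniform random residues to a structure
#'
#' Every position (buried or exposed — burial is emergent from adjacency)
#' receives an independent uniform draw among the 20 residues.
#'
#' @param structure an n x 3 position matrix or a `lattice_antigen` whose
#'   geometry is reused.
#' @param id identity label for the new antigen.
#' @return a `lattice_antigen`.
#' @export
randomize_residues <- function(structure, id = "antigen") {
  pos <- if (inherits(structure, "lattice_antigen")) structure$positions
         else structure
  res <- sample(AA_ALPHABET, nrow(pos), replace = TRUE)
  lattice_antigen(pos, res, id = id)
}

#' Mean binding energy of an antigen against a BCR panel
#'
#' @param antigen `lattice_antigen` or `pose_set`.
#' @param panel character vector of BCR sequences.
#' @param U contact potential.
#' @param s stabilization factor.
#' @param min_contacts forwarded to [enumerate_poses()].
#' @return mean optimal binding energy (kT) over the panel.
#' @export
average_panel_energy <- function(antigen, panel, U = default_potential(),
                                 s = 1.0, min_contacts = 1L) {
  if (length(panel) == 0) stop("panel must be non-empty")
  mean(binding_energy(panel, antigen, U = U, s = s,
                      min_contacts = min_contacts)$energy)
}

#' Immunogenicity class from a mean panel energy
#'
#' Classes partition the energy axis from A (mean energy < -75 kT, most
#' immunogenic) in 2.5-kT steps up to H (mean energy >= -60 kT).  Interval
#' boundaries belong to the right-hand (less immunogenic) class.
#'
#' @param meanE mean panel energy in kT (vectorized, finite).
#' @return character vector of class labels A..H.
#' @examples
#' classify_immunogenicity(c(-76, -68, -59))  # "A" "D" "H"
#' @export
classify_immunogenicity <- function(meanE) {
  if (any(!is.finite(meanE))) stop("mean energy must be finite")
  breaks <- c(-Inf, seq(-75, -60, by = 2.5), Inf)
  labels <- LETTERS[1:8]
  labels[findInterval(meanE, breaks, left.open = FALSE)]
}

#' Assemble a multi-domain antigen set with equal dosing
#'
#' The total antigen dose is divided equally across domains, mirroring a
#' multi-domain antigen whose domains are present in equal amounts on the
#' FDCs.
#'
#' @param antigens list of `lattice_antigen` objects (>= 1, unique ids).
#' @param total_dose total units of antigen (default 3000).
#' @return an `antigen_set` with `domains`, `per_domain_dose`, `total_dose`.
#' @export
build_antigen_set <- function(antigens, total_dose = 3000) {
  if (inherits(antigens, "lattice_antigen")) antigens <- list(antigens)
  if (length(antigens) == 0) stop("at least one antigen is required")
  if (total_dose <= 0) stop("total_dose must be positive")
  stopifnot(all(vapply(antigens, inherits, logical(1), "lattice_antigen")))
  ids <- vapply(antigens, `[[`, character(1), "id")
  if (anyDuplicated(ids))
    stop("antigen ids must be unique within a set: ",
         paste(ids[duplicated(ids)], collapse = ", "))
  structure(list(domains = antigens, per_domain_dose = total_dose / length(antigens),
                 total_dose = total_dose),
            class = "antigen_set")
}

#' @export
print.antigen_set <- function(x, ...) {
  cat("Antigen set:", length(x$domains), "domain(s),", x$per_domain_dose,
      "units each (total", paste0(x$total_dose, ")\n"))
  for (a in x$domains) print(a)
  invisible(x)
}

#' Generate and classify a library of random antigens
#'
#' Assigns random residues to one structure repeatedly, scores each variant's
#' mean binding energy against a random naive BCR panel, and returns the
#' classified library — the screening route by which antigens of chosen
#' immunogenicity classes are obtained.
#'
#' @param structure position matrix or `lattice_antigen` (geometry template).
#' @param count number of random-residue variants (default 1000).
#' @param panel character vector of naive BCR sequences used for scoring, or
#'   an integer to draw that many random sequences of length `L`.
#' @param L BCR length used when `panel` is a count (default 9).
#' @param U contact potential.
#' @param s stabilization factor.
#' @param min_contacts forwarded to [enumerate_poses()].
#' @param id_prefix prefix for antigen ids.
#' @return a list with `antigens` (list of `lattice_antigen` with class
#'   labels) and `table` (data.frame of id, mean_energy, class).
#' @export
antigen_library <- function(structure, count = 1000L, panel = 200L, L = 9L,
                            U = default_potential(), s = 1.0,
                            min_contacts = 1L, id_prefix = "ag") {
  pos <- if (inherits(structure, "lattice_antigen")) structure$positions
         else structure
  if (is.numeric(panel) && length(panel) == 1)
    panel <- random_bcr_panel(panel, L = L)
  antigens <- vector("list", count)
  meanE <- numeric(count)
  codes <- aa_encode(panel)
  for (i in seq_len(count)) {
    ag <- randomize_residues(pos, id = sprintf("%s%03d", id_prefix, i))
    # profiles carry antigen residue letters, so each residue reassignment
    # needs its own enumeration; skip the session cache to bound memory
    psi <- enumerate_poses(ag, L = nchar(panel[1]), min_contacts = min_contacts,
                           cache = FALSE)
    sc <- cpp_score_sequences(psi$ptr, codes, unclass(U), s)
    meanE[i] <- mean(sc$energy)
    ag$class_label <- classify_immunogenicity(meanE[i])
    antigens[[i]] <- ag
  }
  list(antigens = antigens,
       table = data.frame(id = vapply(antigens, `[[`, character(1), "id"),
                          mean_energy = meanE,
                          class = vapply(antigens, `[[`, character(1),
                                         "class_label"),
                          stringsAsFactors = FALSE))
}
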