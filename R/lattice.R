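# Cubic-lattice geometry: chains live on integer coordinates with the
# 6-neighborhood (von Neumann) as the only adjacency.  One node corresponds to
# 5 micrometers in GC space and 5.25 Angstrom in molecular space; the two
# lattices are independent and never mixed.

#' Lattice neighbors of a point
#'
#' @param p integer vector of length 3 (lattice coordinates).
#' @return a 6 x 3 integer matrix, one unit-offset neighbor per row.
#' @examples
#' neighbors(c(0, 0, 0))
#' @export
neighbors <- function(p) {
  stopifnot(length(p) == 3, all(p == round(p)))
  offs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  sweep(offs, 2, as.integer(p), `+`)
}

#' Validate a lattice chain
#'
#' A valid chain is self-avoiding (no node visited twice) and connected
#' (consecutive positions are lattice 6-neighbors).
#'
#' @param positions integer matrix, one row per residue, columns x, y, z.
#' @return `TRUE` or `FALSE`; malformed input returns `FALSE` rather than
#'   raising.
#' @export
validate_chain <- function(positions) {
  if (!is.matrix(positions) || ncol(positions) != 3 || nrow(positions) < 1)
    return(FALSE)
  if (any(positions != round(positions))) return(FALSE)
  key <- paste(positions[, 1], positions[, 2], positions[, 3])
  if (anyDuplicated(key)) return(FALSE)
  if (nrow(positions) == 1) return(TRUE)
  steps <- abs(diff(positions))
  all(rowSums(steps) == 1)
}

#' The 24 proper rotations of the cubic lattice
#'
#' @return list of 24 orthogonal 3x3 integer matrices with determinant +1.
#' @export
lattice_rotations <- function() {
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  out <- list()
  for (pr in perms) {
    P <- diag(3)[pr, ]
    for (sx in c(1, -1)) for (sy in c(1, -1)) for (sz in c(1, -1)) {
      R <- diag(c(sx, sy, sz)) %*% P
      if (abs(det(R) - 1) < 1e-9) out[[length(out) + 1]] <- R
    }
  }
  out
}

#' Read a lattice structure file
#'
#' The plain-text lattice format has one line per residue, `index residue x y
#' z`, with `#` comments.  Consecutive residues must be lattice neighbors and
#' no node may be used twice.
#'
#' @param file path to a lattice structure file.
#' @param id identity label for the antigen; default is the file base name.
#' @return a `lattice_antigen` object (see [lattice_antigen()]).
#' @export
import_structure <- function(file, id = NULL) {
  raw <- readLines(file)
  keep <- !grepl("^\\s*(#|$)", raw)
  lines <- raw[keep]
  lineno <- which(keep)
  if (length(lines) == 0) stop("no residue lines in ", file)
  fields <- strsplit(trimws(lines), "\\s+")
  nf <- lengths(fields)
  if (any(nf != 5))
    stop("malformed line ", lineno[which(nf != 5)[1]], " in ", file,
         ": expected 'index residue x y z'")
  m <- do.call(rbind, fields)
  pos <- matrix(as.integer(m[, 3:5]), ncol = 3)
  if (anyNA(pos))
    stop("malformed line ", lineno[which(is.na(rowSums(pos)))[1]], " in ",
         file, ": non-integer coordinates")
  res <- m[, 2]
  if (!all(res %in% AA_ALPHABET))
    stop("unknown residue letter on line ",
         lineno[which(!res %in% AA_ALPHABET)[1]], " in ", file)
  key <- paste(pos[, 1], pos[, 2], pos[, 3])
  if (anyDuplicated(key))
    stop("duplicate lattice node on line ", lineno[anyDuplicated(key)],
         " in ", file)
  if (nrow(pos) > 1 && any(rowSums(abs(diff(pos))) != 1)) {
    bad <- which(rowSums(abs(diff(pos))) != 1)[1]
    stop("residues on lines ", lineno[bad], " and ", lineno[bad + 1], " in ",
         file, " are not lattice neighbors")
  }
  lattice_antigen(pos, res, id = if (is.null(id)) basename(file) else id)
}

#' Write a lattice structure file
#'
#' @param antigen a `lattice_antigen` object.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
export_structure <- function(antigen, file) {
  stopifnot(inherits(antigen, "lattice_antigen"))
  hdr <- c("# lattice structure: one line per residue 'index residue x y z'",
           paste0("# id: ", antigen$id))
  n <- nrow(antigen$positions)
  body <- sprintf("%d %s %d %d %d", seq_len(n), antigen$residues,
                  antigen$positions[, 1], antigen$positions[, 2],
                  antigen$positions[, 3])
  writeLines(c(hdr, body), file)
  invisible(file)
}
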