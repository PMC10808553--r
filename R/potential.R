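# The amino-acid contact potential.  The packaged default is the Miyazawa &
# Jernigan (1996) statistical contact-energy table (see the resource header in
# inst/extdata/mj1996_contact_potential.txt); any 20x20 symmetric table in the
# same text format can be swapped in.

#' Load an amino-acid contact-potential matrix
#'
#' Reads a whitespace-separated 20x20 contact-energy table (kT units).  The
#' first non-comment line must list the 20 residue letters defining the row
#' and column order of the matrix; `#` lines are comments.  The matrix is
#' validated (symmetric to 1e-9, finite, all 20 standard residues present)
#' and reordered into the package's canonical alphabet.
#'
#' @param file path to the table; default is the packaged Miyazawa-Jernigan
#'   1996 table.
#' @return a 20x20 symmetric numeric matrix with dimnames in canonical
#'   alphabet order, class `contact_potential`.
#' @examples
#' U <- load_potential()
#' U["A", "C"] == U["C", "A"]
#' @export
load_potential <- function(file = NULL) {
  if (is.null(file))
    file <- system.file("extdata", "mj1996_contact_potential.txt",
                        package = "latticeGC", mustWork = TRUE)
  raw <- readLines(file)
  lines <- raw[!grepl("^\\s*(#|$)", raw)]
  if (length(lines) < 21)
    stop("malformed potential file ", file, ": expected a header line of 20 ",
         "residues followed by 20 matrix rows, got ", length(lines), " lines")
  order_aa <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  if (length(order_aa) != 20 || anyDuplicated(order_aa))
    stop("potential header must list 20 distinct residue letters")
  bad <- setdiff(order_aa, AA_ALPHABET)
  if (length(bad) > 0)
    stop("unknown residue letter in potential header: ",
         paste(bad, collapse = ", "))
  vals <- lapply(strsplit(trimws(lines[2:21]), "\\s+"), as.numeric)
  if (any(lengths(vals) != 20))
    stop("potential row ", which(lengths(vals) != 20)[1],
         " does not have 20 entries")
  U <- do.call(rbind, vals)
  if (!all(is.finite(U)))
    stop("non-finite entry in potential at row ",
         which(!is.finite(U), arr.ind = TRUE)[1, 1])
  dimnames(U) <- list(order_aa, order_aa)
  asym <- abs(U - t(U))
  if (max(asym) > 1e-9) {
    ij <- which(asym == max(asym), arr.ind = TRUE)[1, ]
    stop("potential is not symmetric: U(", order_aa[ij[1]], ",",
         order_aa[ij[2]], ") = ", U[ij[1], ij[2]], " but U(", order_aa[ij[2]],
         ",", order_aa[ij[1]], ") = ", U[ij[2], ij[1]])
  }
  U <- U[AA_ALPHABET, AA_ALPHABET]
  class(U) <- c("contact_potential", class(U))
  U
}

#' Contact energy of an amino-acid pair
#'
#' @param a,b single residue letters.
#' @param U a potential matrix from [load_potential()].
#' @return the contact energy U(a, b) in kT; commutative in `a`, `b`.
#' @export
contact_energy <- function(a, b, U = default_potential()) {
  if (!all(c(a, b) %in% AA_ALPHABET))
    stop("unknown residue letter: ",
         paste(setdiff(c(a, b), AA_ALPHABET), collapse = ", "))
  U[a, b]
}

.potential_cache <- new.env(parent = emptyenv())

#' The packaged default contact potential (memoized)
#' @return the default `contact_potential` matrix.
#' @export
default_potential <- function() {
  if (is.null(.potential_cache$U)) .potential_cache$U <- load_potential()
  .potential_cache$U
}
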