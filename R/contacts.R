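#' Contact maps
#'
#' A contact map is a set of unordered bead pairs `(i, j)` that are
#' non-bonded nearest lattice neighbours. On the cubic lattice such pairs
#' necessarily have odd sequence separation, and the minimal geometrically
#' possible separation is `|i - j| = 3`.
#'
#' @param pairs `M x 2` matrix of 1-based bead indices.
#' @return An object of class `contact_map`: an integer matrix with columns
#'   `i < j`, rows sorted lexicographically, duplicates removed.
#' @export
contact_map <- function(pairs) {
  pairs <- as.matrix(pairs)
  if (length(pairs) == 0L) pairs <- matrix(integer(), 0L, 2L)
  if (ncol(pairs) != 2L) stop("`pairs` must have two columns")
  storage.mode(pairs) <- "integer"
  ij <- cbind(pmin(pairs[, 1L], pairs[, 2L]), pmax(pairs[, 1L], pairs[, 2L]))
  if (any(ij[, 2L] - ij[, 1L] < 3L))
    stop("contact pairs must satisfy |i - j| >= 3")
  if (any((ij[, 2L] - ij[, 1L]) %% 2L == 0L))
    stop("contact pairs must have odd sequence separation (lattice parity)")
  ij <- unique(ij)
  ij <- ij[order(ij[, 1L], ij[, 2L]), , drop = FALSE]
  dimnames(ij) <- list(NULL, c("i", "j"))
  structure(ij, class = c("contact_map", "matrix", "array"))
}

#' @export
print.contact_map <- function(x, ...) {
  cat(sprintf("<contact_map> %d contacts\n", nrow(x)))
  invisible(x)
}

#' Enumerate the contacts of a conformation
#'
#' Exhaustive enumeration of all non-bonded nearest-neighbour bead pairs with
#' `|i - j| >= 3` (the only geometrically possible non-bonded neighbours on
#' the cubic lattice).
#'
#' @param conf a [lattice_conformation()].
#' @return A [contact_map()].
#' @examples
#' compute_contacts(straight_rod(10))  # empty
#' @export
compute_contacts <- function(conf) {
  contact_map(.compute_contacts_cpp(unclass_conf(conf)))
}

contact_key <- function(map) {
  if (nrow(map) == 0L) return(integer(0))
  map[, 1L] * 1000L + map[, 2L]
}

#' Fraction of native contacts
#'
#' The folding reaction coordinate Q: the fraction of the native contact map
#' formed in `conf`.
#'
#' @param conf a [lattice_conformation()].
#' @param native the native [contact_map()] (non-empty).
#' @return Numeric in `[0, 1]`, a multiple of `1 / nrow(native)`.
#' @export
fraction_native <- function(conf, native) {
  if (nrow(native) == 0L) stop("native contact map is empty")
  formed <- compute_contacts(conf)
  sum(contact_key(formed) %in% contact_key(native)) / nrow(native)
}

#' Number of non-native contacts
#'
#' Count of formed contacts absent from the native map. Under the Go
#' potential these are energetically neutral; their formation is purely
#' geometric.
#'
#' @inheritParams fraction_native
#' @return Integer count.
#' @export
count_nonnative <- function(conf, native) {
  formed <- compute_contacts(conf)
  sum(!(contact_key(formed) %in% contact_key(native)))
}

#' Absolute contact order
#'
#' Mean sequence separation `|i - j|` over the contacts of a map.
#'
#' @param map a [contact_map()].
#' @return Numeric scalar (dimensionless, in residues).
#' @export
contact_order <- function(map) {
  if (nrow(map) == 0L) return(NA_real_)
  mean(abs(map[, 2L] - map[, 1L]))
}
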