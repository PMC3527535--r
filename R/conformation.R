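#' Lattice chain conformations
#'
#' A lattice conformation is an ordered set of bead positions on the simple
#' cubic lattice: an `N x 3` integer matrix with one row per bead. Bead 1 is
#' the C-terminus by the package's convention and bead `N` the N-terminus.
#' Consecutive beads must occupy nearest-neighbour lattice sites (unit bond
#' length) and no two beads may share a site (excluded volume).
#'
#' @param positions `N x 3` numeric matrix of integer lattice coordinates,
#'   `N >= 4`.
#' @return An object of class `lattice_conformation` (an integer matrix).
#' @examples
#' rod <- straight_rod(10)
#' radius_of_gyration(rod)
#' @export
lattice_conformation <- function(positions) {
  positions <- as.matrix(positions)
  if (ncol(positions) != 3L)
    stop("`positions` must have three columns (x, y, z)")
  if (nrow(positions) < 4L)
    stop("a lattice conformation needs at least 4 beads")
  if (any(positions != round(positions)))
    stop("lattice coordinates must be integers")
  storage.mode(positions) <- "integer"
  dimnames(positions) <- list(NULL, c("x", "y", "z"))
  .validate_conf_cpp(positions)
  structure(positions, class = c("lattice_conformation", "matrix", "array"))
}

#' @rdname lattice_conformation
#' @param x object to test or validate.
#' @export
is_lattice_conformation <- function(x) inherits(x, "lattice_conformation")

#' @rdname lattice_conformation
#' @export
validate_conformation <- function(x) {
  .validate_conf_cpp(unclass_conf(x))
  invisible(x)
}

unclass_conf <- function(x) {
  m <- unclass(x)
  storage.mode(m) <- "integer"
  m
}

#' @export
print.lattice_conformation <- function(x, ...) {
  cat(sprintf("<lattice_conformation> %d beads, bounding box %s\n",
              nrow(x),
              paste(apply(x, 2, function(v) diff(range(v)) + 1L), collapse = " x ")))
  invisible(x)
}

#' Straight-rod conformation
#'
#' A fully extended chain along the x axis; useful as a contact-free and
#' unknotted reference state.
#'
#' @param n number of beads.
#' @return A [lattice_conformation()].
#' @export
straight_rod <- function(n) {
  lattice_conformation(cbind(seq_len(n) - 1L, 0L, 0L))
}

#' Radius of gyration
#'
#' Root-mean-square bead distance from the chain centroid. Lattice units are
#' converted to angstroms with the C-alpha--C-alpha spacing of 3.8 A per
#' lattice unit.
#'
#' @param conf a [lattice_conformation()].
#' @param angstrom report in angstroms (default) or lattice units.
#' @return Numeric scalar.
#' @export
radius_of_gyration <- function(conf, angstrom = TRUE) {
  m <- unclass_conf(conf)
  ctr <- colMeans(m)
  rg <- sqrt(mean(rowSums(sweep(m, 2, ctr)^2)))
  if (angstrom) rg * lattice_spacing_angstrom() else rg
}

#' @rdname radius_of_gyration
#' @export
lattice_spacing_angstrom <- function() 3.8

#' Read and write plain-text conformation files
#'
#' Format: line 1 holds the bead count `N`, followed by `N` lines
#' `index x y z` of integers with 1-based bead indices. Round-trips are
#' bit-exact.
#'
#' @param path file path.
#' @return `read_conformation()` returns a [lattice_conformation()];
#'   `write_conformation()` returns `path` invisibly.
#' @export
read_conformation <- function(path) {
  lines <- readLines(path)
  n <- as.integer(lines[[1L]])
  tab <- read.table(text = lines[seq(2L, 1L + n)], col.names = c("index", "x", "y", "z"))
  if (!identical(as.integer(tab$index), seq_len(n)))
    stop("conformation file has non-sequential bead indices: ", path)
  lattice_conformation(as.matrix(tab[, c("x", "y", "z")]))
}

#' @rdname read_conformation
#' @param conf a [lattice_conformation()] to write.
#' @export
write_conformation <- function(conf, path) {
  m <- unclass_conf(conf)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(as.character(nrow(m)), con)
  writeLines(sprintf("%d %d %d %d", seq_len(nrow(m)), m[, 1], m[, 2], m[, 3]), con)
  invisible(path)
}
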