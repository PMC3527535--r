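#' Close an open chain into a polygon
#'
#' Both termini are extended radially outward from the chain centroid to a
#' sphere of radius three times the chain's maximal extent and joined by an
#' arc on that sphere. The closure is deterministic, keeps well away from
#' the chain, and the resulting closed polygon is verified to be simple
#' (non-self-intersecting). Degenerate geometry (a terminus at the centroid)
#' falls back to a fixed jittered direction.
#'
#' @param conf a [lattice_conformation()] or an `N x 3` numeric matrix of
#'   open-chain vertices.
#' @return A numeric matrix of polygon vertices of class `closed_polygon`;
#'   the last vertex connects back to the first.
#' @export
close_chain <- function(conf) {
  if (inherits(conf, "closed_polygon"))
    stop("input is already a closed polygon; closure applies to open chains")
  m <- conf
  if (is_lattice_conformation(conf)) m <- unclass_conf(conf)
  m <- matrix(as.double(as.matrix(m)), ncol = 3L)
  structure(.close_chain_cpp(m), class = c("closed_polygon", "matrix", "array"))
}

#' KMT reduction of a closed polygon
#'
#' Repeatedly deletes a vertex whenever the triangle spanned by the vertex
#' and its two neighbours is intersected by no other polygon segment
#' (collinear vertices are deleted unconditionally), iterating to a fixed
#' point. The knot type is invariant under the reduction; the intersection
#' test is conservative, so doubtful deletions are skipped rather than
#' risked.
#'
#' @param polygon a closed polygon ([close_chain()]) or an `M x 3` matrix.
#' @return The reduced polygon (class `closed_polygon`).
#' @export
kmt_reduce <- function(polygon) {
  m <- matrix(as.double(as.matrix(polygon)), ncol = 3L)
  structure(.kmt_reduce_cpp(m), class = c("closed_polygon", "matrix", "array"))
}

#' Alexander determinant of a closed polygon
#'
#' Projects the polygon along a generic direction (deterministically
#' perturbed until the crossing diagram is non-degenerate), builds the
#' Alexander matrix at `t = -1`, and returns the absolute determinant of its
#' minor. The computation is repeated along `n_dirs` projection directions,
#' which must agree. `|Delta(-1)|` is 1 for the unknot, 3 for the trefoil
#' and 5 for the figure-eight knot; it is chirality-blind.
#'
#' @param polygon a closed polygon or an `M x 3` matrix.
#' @param n_dirs number of independent projection directions.
#' @return A non-negative integer, `|Delta(-1)|`.
#' @export
alexander_det <- function(polygon, n_dirs = 3L) {
  m <- matrix(as.double(as.matrix(polygon)), ncol = 3L)
  .alexander_det_cpp(m, as.integer(n_dirs))
}

#' Knottedness report for an open lattice chain
#'
#' Applies the full detection pipeline -- closure, KMT reduction, Alexander
#' determinant -- and, for knotted chains, localizes the knotted core.
#'
#' @param conf a [lattice_conformation()].
#' @param locate_core also run the (more expensive) core localization.
#' @return A list of class `knot_report`: `knotted`, `alexander_det`,
#'   `type_label` (`"unknot"`, `"trefoil"`, `"other"`), and `core_range`
#'   (1-based `(start, end)` or `NULL`).
#' @export
knot_report <- function(conf, locate_core = FALSE) {
  det <- .chain_alexander_cpp(unclass_conf(conf))
  core <- NULL
  if (locate_core && det != 1L) {
    cr <- .knot_core_cpp(unclass_conf(conf))
    if (cr[1] > 0L) core <- c(start = cr[1], end = cr[2])
  }
  structure(list(
    knotted = det != 1L,
    alexander_det = det,
    type_label = if (det == 1L) "unknot" else if (det == 3L) "trefoil" else "other",
    core_range = core
  ), class = "knot_report")
}

#' @export
print.knot_report <- function(x, ...) {
  cat(sprintf("<knot_report> %s (|Delta(-1)| = %d)%s\n", x$type_label,
              x$alexander_det,
              if (!is.null(x$core_range))
                sprintf(", core beads %d-%d", x$core_range[1], x$core_range[2])
              else ""))
  invisible(x)
}

#' Minimal knotted segment of a chain
#'
#' Shrinks a knotted chain to the smallest contiguous bead range whose
#' sub-chain, closed by the same convention, is still knotted: beads are
#' deleted one at a time from alternating ends, re-closing and re-testing
#' after each deletion, until any further deletion unties the knot.
#'
#' @param conf a knotted [lattice_conformation()].
#' @return Integer vector `c(start, end)` of 1-based bead indices.
#' @export
find_knot_core <- function(conf) {
  cr <- .knot_core_cpp(unclass_conf(conf))
  if (cr[1] == 0L)
    stop("chain is not knotted after closure; no knotted core to localize")
  c(start = cr[1], end = cr[2])
}

#' Bundled closed lattice knot polygons
#'
#' Reference closed polygons on the cubic lattice, produced by tracing the
#' parametric knots onto the lattice and shortening the resulting polygons
#' with knot-type-preserving moves: a 24-edge trefoil (the minimal possible
#' edge count for a lattice trefoil) and a 38-edge figure-eight knot. Their
#' Alexander determinants are 3 and 5.
#'
#' @return An `M x 3` integer matrix of closed-polygon vertices (the last
#'   vertex connects back to the first).
#' @export
lattice_trefoil_polygon <- function() read_polygon_fixture("trefoil_polygon_24")

#' @rdname lattice_trefoil_polygon
#' @export
lattice_figure_eight_polygon <- function() read_polygon_fixture("figure_eight_polygon_38")

read_polygon_fixture <- function(name) {
  path <- system.file("extdata", paste0(name, ".txt"), package = "knotfold",
                      mustWork = TRUE)
  lines <- readLines(path)
  n <- as.integer(lines[[1L]])
  tab <- read.table(text = lines[seq(2L, 1L + n)],
                    col.names = c("index", "x", "y", "z"))
  as.matrix(tab[, c("x", "y", "z")])
}

#' Knotting probability as a function of nativeness
#'
#' For conformations grouped by their fraction of native contacts Q, the
#' fraction whose closure is knotted, with binomial standard errors.
#'
#' @param ensembles a named list: names are Q values, elements are lists of
#'   [lattice_conformation()]s (see [harvest_ensemble()]).
#' @return A data frame of class `p_knot_curve` with columns `q`, `n`,
#'   `p_knot`, `stderr`. Empty groups are dropped with a warning.
#' @export
p_knot_curve <- function(ensembles) {
  keep <- vapply(ensembles, length, integer(1)) > 0L
  if (any(!keep)) {
    warning("dropping empty Q groups: ",
            paste(names(ensembles)[!keep], collapse = ", "))
    ensembles <- ensembles[keep]
  }
  rows <- lapply(names(ensembles), function(qname) {
    confs <- lapply(ensembles[[qname]], unclass_conf)
    det <- .batch_alexander_cpp(confs)
    n <- length(det)
    p <- mean(det != 1L)
    data.frame(q = as.numeric(qname), n = n, p_knot = p,
               stderr = sqrt(p * (1 - p) / n))
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$q), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("p_knot_curve", "data.frame")
  out
}
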