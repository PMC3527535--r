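#' Folding setups: bulk, plane-tethered, point-tethered
#'
#' A folding setup describes the external constraints on the chain:
#' \describe{
#'   \item{`bulk`}{free folding, no constraints.}
#'   \item{`plane_tether`}{one terminus is linked to a chemically inert plane
#'     at `z = 0` by a linker of one lattice spacing: the anchored bead is
#'     permanently fixed at `(0, 0, 1)` and every bead must keep `z >= 1`
#'     (the wall is purely steric). Tethering also removes the end-move of
#'     the anchored terminus.}
#'   \item{`point_tether`}{the anchored bead is fixed at `anchor_site` but
#'     there is no wall (the control experiment separating the steric effect
#'     of the plane from the loss of terminus mobility).}
#' }
#'
#' @param mode one of `"bulk"`, `"plane_tether"`, `"point_tether"`.
#' @param anchored_bead which terminus is anchored: `1` (the C-terminus) or
#'   `n_beads` (the N-terminus). Ignored for `"bulk"`.
#' @param n_beads chain length, required to anchor the last bead.
#' @param anchor_site fixed lattice site of the anchored bead. Defaults to
#'   `(0, 0, 1)`, one lattice spacing above the tether point at the origin.
#' @return An object of class `folding_setup`.
#' @examples
#' folding_setup("bulk")
#' folding_setup("plane_tether", anchored_bead = 1)
#' @export
folding_setup <- function(mode = c("bulk", "plane_tether", "point_tether"),
                          anchored_bead = NULL, n_beads = NULL,
                          anchor_site = c(0L, 0L, 1L)) {
  mode <- match.arg(mode)
  if (mode == "bulk") {
    out <- list(mode = mode, anchored_bead = NA_integer_,
                anchor_site = NULL, wall = FALSE)
  } else {
    if (is.null(anchored_bead))
      stop("tethered setups need `anchored_bead` (1 or the last bead)")
    anchored_bead <- as.integer(anchored_bead)
    anchor_site <- as.integer(anchor_site)
    if (mode == "plane_tether") {
      if (!identical(anchor_site, c(0L, 0L, 1L)))
        stop("plane tethering fixes the anchored bead at (0, 0, 1), one lattice spacing above the wall")
      if (anchor_site[3] < 1L) stop("anchored bead must sit above the wall")
    }
    out <- list(mode = mode, anchored_bead = anchored_bead,
                anchor_site = anchor_site, wall = mode == "plane_tether")
  }
  structure(out, class = "folding_setup")
}

#' @export
print.folding_setup <- function(x, ...) {
  if (x$mode == "bulk") cat("<folding_setup> bulk\n")
  else cat(sprintf("<folding_setup> %s, bead %d fixed at (%s)%s\n",
                   x$mode, x$anchored_bead,
                   paste(x$anchor_site, collapse = ", "),
                   if (x$wall) ", steric wall at z = 0" else ""))
  invisible(x)
}

# map to the C++ enum and a 1-based anchored index (0 = none)
setup_mode_code <- function(setup) {
  switch(setup$mode, bulk = 0L, plane_tether = 1L, point_tether = 2L)
}
setup_anchor_index <- function(setup, n_beads) {
  if (setup$mode == "bulk") return(0L)
  b <- setup$anchored_bead
  if (!(b %in% c(1L, n_beads)))
    stop("`anchored_bead` must be a terminus (1 or ", n_beads, ")")
  b
}

# check a conformation against a setup (anchor position, wall clearance)
check_setup_conf <- function(conf, setup) {
  m <- unclass_conf(conf)
  if (setup$mode != "bulk") {
    b <- setup_anchor_index(setup, nrow(m))
    if (!identical(as.integer(m[b, ]), setup$anchor_site))
      stop("anchored bead ", b, " is not at the anchor site (",
           paste(setup$anchor_site, collapse = ", "), ")")
  }
  if (isTRUE(setup$wall) && any(m[, 3] < 1L))
    stop("conformation violates the steric wall: all beads need z >= 1")
  invisible(conf)
}
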