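#' Propose elementary Monte Carlo moves
#'
#' Draws elementary move attempts from the local move set: with probability
#' `p_crank` a crankshaft (beads `i+1`, `i+2` rotated by 90, 180 or 270
#' degrees about the axis through beads `i` and `i+3` when those are lattice
#' neighbours along an axis), otherwise a single-bead move at a uniformly
#' chosen bead -- an end-move for a non-anchored terminus (relocation to a
#' uniformly chosen vacant neighbour of its bonded neighbour) or a corner
#' flip for an interior bead with perpendicular bonds. Infeasible draws
#' (collinear bonds, occupied targets, wall violations, the anchored bead)
#' are "no-moves": attempted but rejected steps, which keeps the proposal
#' distribution symmetric and detailed balance intact.
#'
#' @param conf a [lattice_conformation()] valid under `setup`.
#' @param setup a [folding_setup()].
#' @param n_attempts number of independent attempts to draw.
#' @param p_crank crankshaft attempt probability.
#' @param seed integer seed for the proposal stream.
#' @return A list of length `n_attempts`: each element is a candidate
#'   [lattice_conformation()] or `NULL` for a no-move.
#' @export
propose_move <- function(conf, setup = folding_setup("bulk"), n_attempts = 1L,
                         p_crank = 0.2, seed = 1L) {
  check_setup_conf(conf, setup)
  m <- unclass_conf(conf)
  out <- .propose_moves_cpp(m, setup_mode_code(setup),
                            setup_anchor_index(setup, nrow(m)),
                            p_crank, as.double(seed), as.integer(n_attempts))
  lapply(out, function(x) if (is.null(x)) NULL else lattice_conformation(x))
}

#' Enumerate all legal single-move candidates
#'
#' Exhaustively lists every distinct conformation reachable by one legal
#' elementary move (all single-bead moves and all crankshafts). Intended for
#' reversibility and proposal-coverage checks on short chains.
#'
#' @inheritParams propose_move
#' @return A list of candidate [lattice_conformation()]s.
#' @export
enumerate_moves <- function(conf, setup = folding_setup("bulk")) {
  m <- unclass_conf(conf)
  out <- .enumerate_moves_cpp(m, setup_mode_code(setup),
                              setup_anchor_index(setup, nrow(m)))
  lapply(out, lattice_conformation)
}
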