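#' Random unfolded start conformations
#'
#' Generates a random self-avoiding conformation by seeded chain growth
#' (uniform among legal extensions, restarting on dead ends), honouring the
#' tether constraints of `setup`, and rejecting candidates that are already
#' partly native (`Q > max_q`).
#'
#' @param n_beads chain length.
#' @param setup a [folding_setup()]. For tethered setups the chain is grown
#'   from the anchor site so the anchored terminus ends up fixed there.
#' @param native optional native [contact_map()] used for the `Q` rejection
#'   rule; with `NULL` no rejection is applied.
#' @param max_q largest admissible fraction of native contacts in the start.
#' @param seed integer seed.
#' @param max_tries growth/rejection retry budget.
#' @return A [lattice_conformation()].
#' @export
random_unfolded <- function(n_beads, setup = folding_setup("bulk"), native = NULL,
                            max_q = 0.2, seed = 1L, max_tries = 1000L) {
  n_beads <- as.integer(n_beads)
  origin <- if (setup$mode == "bulk") c(0L, 0L, 0L) else setup$anchor_site
  anchored <- if (setup$mode == "bulk") 0L else setup_anchor_index(setup, n_beads)
  for (k in seq_len(max_tries)) {
    m <- .grow_saw_cpp(n_beads, origin, isTRUE(setup$wall),
                       reverse_order = anchored == n_beads,
                       seed = as.double(seed) * 1e6 + k, max_restarts = 1000L)
    conf <- lattice_conformation(m)
    if (is.null(native) || fraction_native(conf, native) <= max_q)
      return(conf)
  }
  stop("failed to generate an unfolded start with Q <= ", max_q,
       " after ", max_tries, " tries")
}

#' Fixed-temperature Monte Carlo folding run
#'
#' Runs a Metropolis chain under the Go potential from a random unfolded
#' start (or a supplied one), recording a trajectory of
#' `(time, energy, Q, Rg, n_nonnative)` every `record_interval` attempted
#' moves (1 MCS = one attempted elementary move). The run stops at the first
#' passage to `Q = 1` when `stop_at_fold` is `TRUE`; otherwise it runs to
#' `max_steps`.
#'
#' @param native a `native_structure` (see [design_knotted_native()]) or any
#'   list with elements `conformation` and `native_map`.
#' @param temperature temperature in `|epsilon|/k_B` units.
#' @param max_steps total budget in MCS.
#' @param record_interval trajectory recording interval in MCS.
#' @param snapshot_interval coordinate snapshot interval in MCS (0 = none).
#' @param setup a [folding_setup()].
#' @param p_crank crankshaft attempt probability.
#' @param seed integer seed (one seeded generator drives the whole run).
#' @param start optional start conformation; default is a fresh
#'   [random_unfolded()] draw.
#' @param stop_at_fold stop at the first passage to `Q = 1`.
#' @param debug_checks re-derive the contact bookkeeping from scratch at
#'   every recording point and fail loudly on divergence.
#' @return A list of class `folding_run`: `trajectory` (data frame),
#'   `folded`, `fpt` (first-passage time in MCS or `NA`), `final`
#'   conformation, `snapshots` (list of conformations), `snapshot_time`,
#'   `snapshot_q`, `acceptance`, and the run parameters.
#' @export
run_folding <- function(native, temperature, max_steps, record_interval = 1e4,
                        snapshot_interval = 0, setup = folding_setup("bulk"),
                        p_crank = 0.2, seed = 1L, start = NULL,
                        stop_at_fold = TRUE, debug_checks = FALSE) {
  stopifnot(max_steps > 0, record_interval <= max_steps)
  nat_conf <- unclass_conf(native$conformation)
  n_beads <- nrow(nat_conf)
  if (is.null(start))
    start <- random_unfolded(n_beads, setup, native$native_map, seed = seed)
  check_setup_conf(start, setup)
  res <- .run_mc_cpp(unclass_conf(start), unclass(native$native_map), temperature,
                     as.double(max_steps), as.double(record_interval),
                     as.double(snapshot_interval), setup_mode_code(setup),
                     setup_anchor_index(setup, n_beads), p_crank,
                     as.double(seed), stop_at_fold, debug_checks)
  traj <- as.data.frame(res$trajectory)
  names(traj) <- c("time", "energy", "Q", "Rg", "n_nonnative")
  traj$Rg <- traj$Rg * lattice_spacing_angstrom()
  traj$knotted <- NA
  n_snap <- length(res$snapshot_time)
  snaps <- vector("list", n_snap)
  if (n_snap > 0) {
    # engine output is valid by construction; skip constructor validation
    for (s in seq_len(n_snap))
      snaps[[s]] <- structure(matrix(res$snapshots[s, ], ncol = 3L, byrow = TRUE,
                                     dimnames = list(NULL, c("x", "y", "z"))),
                              class = c("lattice_conformation", "matrix", "array"))
  }
  structure(list(
    trajectory = traj,
    folded = res$folded,
    fpt = res$fpt,
    final = lattice_conformation(res$final),
    snapshots = snaps,
    snapshot_time = res$snapshot_time,
    snapshot_q = if (n_snap > 0) res$snapshot_formed / nrow(native$native_map) else numeric(0),
    acceptance = res$n_accept / max(1, max_steps),
    params = list(temperature = temperature, max_steps = max_steps,
                  record_interval = record_interval,
                  snapshot_interval = snapshot_interval,
                  setup = setup, p_crank = p_crank, seed = seed)
  ), class = "folding_run")
}

#' @export
print.folding_run <- function(x, ...) {
  cat(sprintf("<folding_run> T = %g, %s after %s MCS (%d records)\n",
              x$params$temperature,
              if (x$folded) sprintf("folded at t = %g", x$fpt) else "unfolded at budget",
              format(x$params$max_steps, scientific = TRUE),
              nrow(x$trajectory)))
  invisible(x)
}

#' Trajectory file input/output
#'
#' Tab-separated trajectory files with a header row and columns
#' `time`, `energy`, `Q`, `Rg_angstrom`, `n_nonnative`, `knotted` (0/1/NA).
#'
#' @param trajectory a trajectory data frame from [run_folding()].
#' @param path file path.
#' @return `read_trajectory()` returns the data frame; `write_trajectory()`
#'   returns `path` invisibly.
#' @export
write_trajectory <- function(trajectory, path) {
  out <- data.frame(time = trajectory$time, energy = trajectory$energy,
                    Q = trajectory$Q, Rg_angstrom = trajectory$Rg,
                    n_nonnative = trajectory$n_nonnative,
                    knotted = as.integer(trajectory$knotted))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  tab <- read.table(path, header = TRUE, sep = "\t")
  data.frame(time = tab$time, energy = tab$energy, Q = tab$Q,
             Rg = tab$Rg_angstrom, n_nonnative = tab$n_nonnative,
             knotted = tab$knotted)
}
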