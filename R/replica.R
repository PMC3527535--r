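#' Geometric temperature grid for replica exchange
#'
#' `n` temperatures spaced at a constant ratio between `t_low` and `t_high`.
#' The grid should bracket the expected melting temperature; a dense grid
#' keeps the exchange acceptance near one.
#'
#' @param t_low,t_high grid bounds, `0 < t_low < t_high`.
#' @param n number of temperatures (default 40).
#' @return Numeric vector of length `n`, strictly increasing.
#' @export
build_temperature_grid <- function(t_low, t_high, n = 40L) {
  if (!(t_low > 0 && t_high > t_low)) stop("need 0 < t_low < t_high")
  if (n < 2L) stop("need at least two temperatures")
  exp(seq(log(t_low), log(t_high), length.out = n))
}

#' Replica-exchange Monte Carlo sampling
#'
#' Parallel tempering across a temperature grid: every sweep advances each
#' replica by `sweep_steps` elementary moves at its current temperature, then
#' attempts `swaps_per_sweep` exchanges between randomly chosen adjacent
#' temperature pairs with acceptance
#' `min(1, exp[(1/T_i - 1/T_j)(E_i - E_j)])`. Energy, Q and Rg are sampled
#' once per sweep at every temperature; the first `equilibration` fraction of
#' sweeps is discarded from the returned samples.
#'
#' @inheritParams run_folding
#' @param temperatures strictly increasing temperature grid (see
#'   [build_temperature_grid()]).
#' @param sweep_steps elementary move attempts per replica per sweep (MCS).
#' @param n_sweeps number of sweeps.
#' @param swaps_per_sweep exchange attempts per sweep (default: one per
#'   adjacent pair on average).
#' @param equilibration fraction of initial sweeps discarded (default 0.2).
#' @param start optional start conformation shared by all replicas; default
#'   is a fresh [random_unfolded()] draw per replica.
#' @return A list of class `replica_exchange`: matrices `energy`, `q`, `rg`
#'   (post-equilibration sweeps x temperatures), `temperatures`,
#'   `swap_acceptance` (per adjacent pair), `replica_history`, `round_trips`
#'   (per replica count of full cold-to-hot-to-cold cycles), and `params`.
#' @export
run_replica_exchange <- function(native, temperatures, sweep_steps, n_sweeps,
                                 swaps_per_sweep = length(temperatures),
                                 setup = folding_setup("bulk"), p_crank = 0.2,
                                 equilibration = 0.2, seed = 1L, start = NULL) {
  if (is.unsorted(temperatures, strictly = TRUE))
    stop("`temperatures` must be strictly increasing")
  n_beads <- nrow(unclass_conf(native$conformation))
  starts <- vector("list", length(temperatures))
  for (k in seq_along(temperatures)) {
    starts[[k]] <- if (!is.null(start)) unclass_conf(start)
    else unclass_conf(random_unfolded(n_beads, setup, native$native_map,
                                      seed = seed + 7919L * k))
    if (!is.null(start)) check_setup_conf(start, setup)
  }
  res <- .run_re_cpp(starts, unclass(native$native_map), temperatures,
                     as.double(sweep_steps), as.integer(n_sweeps),
                     as.integer(swaps_per_sweep), setup_mode_code(setup),
                     setup_anchor_index(setup, n_beads), p_crank,
                     as.double(seed))
  keep <- seq.int(floor(n_sweeps * equilibration) + 1L, n_sweeps)
  hist <- res$replica_history
  structure(list(
    energy = res$energy[keep, , drop = FALSE],
    q = res$q[keep, , drop = FALSE],
    rg = res$rg[keep, , drop = FALSE] * lattice_spacing_angstrom(),
    temperatures = temperatures,
    swap_acceptance = res$swap_acceptance,
    replica_history = hist,
    round_trips = count_round_trips(hist),
    params = list(sweep_steps = sweep_steps, n_sweeps = n_sweeps,
                  swaps_per_sweep = swaps_per_sweep, setup = setup,
                  p_crank = p_crank, equilibration = equilibration,
                  seed = seed)
  ), class = "replica_exchange")
}

# full cold -> hot -> cold cycles completed by each replica
count_round_trips <- function(replica_history) {
  k <- ncol(replica_history)
  vapply(seq_len(k), function(r) {
    at <- apply(replica_history == r, 1L, which.max)  # temp slot of replica r
    seen_hot <- FALSE
    trips <- 0L
    for (t in at) {
      if (t == k) seen_hot <- TRUE
      if (t == 1L && seen_hot) { trips <- trips + 1L; seen_hot <- FALSE }
    }
    trips
  }, integer(1))
}

#' Pool replicate replica-exchange runs
#'
#' Concatenates the post-equilibration samples of independent
#' replica-exchange runs over the same temperature grid, so downstream
#' estimators (heat capacity, WHAM) average over replicates.
#'
#' @param re_list list of `replica_exchange` objects sharing a grid.
#' @return A pooled `replica_exchange` object.
#' @export
pool_replica_exchange <- function(re_list) {
  stopifnot(length(re_list) >= 1L)
  temps <- re_list[[1L]]$temperatures
  for (re in re_list)
    if (!isTRUE(all.equal(re$temperatures, temps)))
      stop("replicate runs must share one temperature grid")
  pooled <- re_list[[1L]]
  pooled$energy <- do.call(rbind, lapply(re_list, `[[`, "energy"))
  pooled$q <- do.call(rbind, lapply(re_list, `[[`, "q"))
  pooled$rg <- do.call(rbind, lapply(re_list, `[[`, "rg"))
  pooled$swap_acceptance <-
    rowMeans(vapply(re_list, `[[`, numeric(length(temps) - 1L), "swap_acceptance"))
  pooled$round_trips <- Reduce(`+`, lapply(re_list, `[[`, "round_trips"))
  pooled$replica_history <- NULL
  pooled$params$replicates <- length(re_list)
  pooled
}

#' @export
print.replica_exchange <- function(x, ...) {
  cat(sprintf(
    "<replica_exchange> %d temperatures in [%.3g, %.3g], %d retained sweeps\n",
    length(x$temperatures), min(x$temperatures), max(x$temperatures),
    nrow(x$energy)))
  cat(sprintf("  mean adjacent swap acceptance %.3f, %d round trips\n",
              mean(x$swap_acceptance), sum(x$round_trips)))
  invisible(x)
}
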