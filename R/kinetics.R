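#' Collect first-passage times from folding runs
#'
#' Aggregates the outcomes of independent fixed-temperature folding runs into
#' first-passage-time statistics. Foldicity is the fraction of attempted runs
#' that reached the native state within the budget; unsuccessful runs are
#' kept as censored observations (they remain "unfolded" through the budget
#' when the survival curve is built).
#'
#' @param runs a list of `folding_run` objects ([run_folding()]), or a data
#'   frame with columns `folded` (logical) and `fpt`.
#' @return A list of class `kinetics_result`: `fpt` (times of folded runs),
#'   `n_attempted`, `n_folded`, `foldicity`, `budget` (common run budget),
#'   `rate` (unset, see [fit_rate()]).
#' @export
collect_fpts <- function(runs) {
  if (is.data.frame(runs)) {
    folded <- runs$folded
    fpt <- runs$fpt
    budget <- attr(runs, "budget")
    if (is.null(budget)) budget <- max(runs$budget)
  } else {
    folded <- vapply(runs, function(r) isTRUE(r$folded), logical(1))
    fpt <- vapply(runs, function(r) as.double(r$fpt), double(1))
    budgets <- vapply(runs, function(r) r$params$max_steps, double(1))
    temps <- vapply(runs, function(r) r$params$temperature, double(1))
    if (length(unique(budgets)) > 1L || length(unique(temps)) > 1L)
      stop("folding runs differ in budget or temperature; collect runs that share parameters")
    budget <- budgets[1L]
  }
  structure(list(
    fpt = sort(fpt[folded]),
    n_attempted = length(folded),
    n_folded = sum(folded),
    foldicity = sum(folded) / length(folded),
    budget = budget,
    rate = NULL
  ), class = "kinetics_result")
}

#' @export
print.kinetics_result <- function(x, ...) {
  cat(sprintf("<kinetics_result> %d/%d folded (foldicity %.1f%%)",
              x$n_folded, x$n_attempted, 100 * x$foldicity))
  if (!is.null(x$rate)) cat(sprintf(", k = %.3g / MCS", x$rate))
  cat("\n")
  invisible(x)
}

#' Survival curve of the unfolded population
#'
#' Fraction of runs still unfolded as a function of MC time. Censored runs
#' contribute to the unfolded fraction up to the budget.
#'
#' @param result a `kinetics_result` ([collect_fpts()]).
#' @param times evaluation time grid; defaults to the sorted first-passage
#'   times.
#' @return Data frame with columns `time`, `p_unfolded`.
#' @export
survival_curve <- function(result, times = NULL) {
  if (is.null(times)) times <- result$fpt
  p <- vapply(times, function(t) 1 - sum(result$fpt <= t) / result$n_attempted,
              double(1))
  data.frame(time = times, p_unfolded = p)
}

#' Folding rate from a single-exponential fit
#'
#' The folding rate is the negative slope of an unweighted least-squares fit
#' of `log P_unfolded(t)` against `t`, over the window where the unfolded
#' fraction lies in `[p_floor, 1)`. This matches a single-exponential decay
#' of the population of proteins that remain unfolded, and tolerates
#' incomplete foldicity (censored runs keep the survival curve up).
#'
#' @param result a `kinetics_result`.
#' @param p_floor lower survival bound of the fit window (default 0.05;
#'   the far tail is excluded as noise-dominated).
#' @param min_folded refusal floor: the fit is not attempted with fewer
#'   folded runs.
#' @return The input with `rate` (in 1/MCS), `fit` (`r_squared`,
#'   `n_points`), and `survival` filled in.
#' @export
fit_rate <- function(result, p_floor = 0.05, min_folded = 50L) {
  if (result$n_folded < min_folded)
    stop(sprintf("rate fit refused: only %d folded runs (floor %d)",
                 result$n_folded, min_folded))
  sc <- survival_curve(result)
  sel <- sc$p_unfolded >= p_floor & sc$p_unfolded < 1 & sc$time > 0
  if (sum(sel) < 3L) stop("too few survival points in the fit window")
  fit <- lm(log(p_unfolded) ~ time, data = sc[sel, ])
  slope <- unname(coef(fit)[2L])
  if (!(slope < 0)) stop("survival curve is not decaying; no rate")
  result$rate <- -slope
  result$fit <- list(
    r_squared = summary(fit)$r.squared,
    n_points = sum(sel),
    p_floor = p_floor)
  result$survival <- sc
  result
}
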