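#' Heat capacity from energy fluctuations
#'
#' `Cv(T) = (<E^2> - <E>^2) / (k_B T^2)` with `k_B = 1`, evaluated from the
#' energy samples at each temperature of a replica-exchange run.
#'
#' @param x a `replica_exchange` object, or a numeric matrix of energy
#'   samples with one column per temperature.
#' @param temperatures required when `x` is a matrix.
#' @return A data frame of class `cv_curve` with columns `temperature`, `cv`.
#' @export
heat_capacity <- function(x, temperatures = NULL) {
  if (inherits(x, "replica_exchange")) {
    energy <- x$energy
    temperatures <- x$temperatures
  } else {
    energy <- as.matrix(x)
    if (is.null(temperatures)) stop("`temperatures` needed with a sample matrix")
  }
  if (nrow(energy) < 2L) stop("need at least two energy samples per temperature")
  v <- apply(energy, 2L, function(e) mean(e^2) - mean(e)^2)
  out <- data.frame(temperature = temperatures, cv = v / temperatures^2)
  class(out) <- c("cv_curve", "data.frame")
  out
}

#' Melting temperature
#'
#' The temperature at which the heat capacity attains its maximum. Ties are
#' broken towards the lower temperature (with a message).
#'
#' @param cv_curve a data frame with columns `temperature` and `cv`.
#' @return The melting temperature Tm (an element of the grid).
#' @export
estimate_tm <- function(cv_curve) {
  if (nrow(cv_curve) == 0L) stop("empty heat-capacity curve")
  mx <- max(cv_curve$cv)
  hits <- which(cv_curve$cv == mx)
  if (length(hits) > 1L)
    message("heat-capacity maximum is tied; taking the lowest temperature")
  cv_curve$temperature[min(hits)]
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# self-consistent WHAM free-energy shifts over discrete energy levels
wham_shifts <- function(energy, temperatures, tol = 1e-7, max_iter = 1e5) {
  k <- length(temperatures)
  beta <- 1 / temperatures
  lev <- sort(unique(as.vector(energy)))
  # adjacent-histogram overlap diagnostic
  for (i in seq_len(k - 1L)) {
    ri <- range(energy[, i]); rj <- range(energy[, i + 1L])
    if (ri[1] > rj[2] || rj[1] > ri[2])
      stop(sprintf(
        "energy histograms at temperatures %g and %g do not overlap (E ranges [%g, %g] vs [%g, %g])",
        temperatures[i], temperatures[i + 1L], ri[1], ri[2], rj[1], rj[2]))
  }
  h <- vapply(lev, function(l) sum(energy == l), numeric(1))   # pooled histogram
  n_i <- rep(nrow(energy), k)
  f <- numeric(k)
  bl <- outer(beta, lev)                                        # k x L matrix beta_i * E_l
  log_n <- log(n_i)
  for (it in seq_len(max_iter)) {
    # log denominator per level: logsumexp_i (log n_i + f_i - beta_i E_l)
    denom <- apply(log_n + f - bl, 2L, logsumexp)
    log_p <- log(h) - denom
    f_new <- -vapply(seq_len(k), function(i) logsumexp(log_p - bl[i, ]), numeric(1))
    f_new <- f_new - f_new[1L]
    if (max(abs(f_new - f)) < tol) {
      f <- f_new
      break
    }
    f <- f_new
  }
  list(f = f, levels = lev, iterations = it)
}

# log reweighting factor per energy level at inverse temperature beta_t
wham_level_logw <- function(shifts, beta, beta_t, n_per_temp) {
  lev <- shifts$levels
  bl <- outer(beta, lev)
  denom <- apply(log(n_per_temp) + shifts$f - bl, 2L, logsumexp)
  -beta_t * lev - denom
}

#' WHAM free-energy surfaces and profiles
#'
#' Combines replica-exchange samples with the multiple-histogram (WHAM)
#' estimator: per-temperature free-energy shifts are iterated to
#' self-consistency (tolerance `1e-7`, at most `1e5` iterations), then every
#' sample is reweighted to the target temperature and binned over the
#' requested reaction coordinate(s). `F = -T log(density)`, shifted so the
#' minimum is zero; cells with no support are `NA`.
#'
#' Energy is exactly discrete under the Go potential and is binned at its
#' integer levels; `Q` at its exact multiples of `1/n_native`; `Rg` in bins
#' of 0.5 angstrom.
#'
#' @param re a `replica_exchange` object ([run_replica_exchange()]).
#' @param coords `"q"` for the one-dimensional profile F(Q), or `"e_rg"` for
#'   the surface over (energy, gyration radius).
#' @param t_target temperature at which the free energy is evaluated.
#' @param tol,max_iter WHAM self-consistency controls.
#' @return For `"q"`: a data frame of class `free_energy_profile` with
#'   columns `q`, `f`, `weight`. For `"e_rg"`: a list of class
#'   `free_energy_surface` with `energy_levels`, `rg_breaks`, and matrix `f`.
#'   Both carry attributes `t_target` and `shifts`.
#' @export
wham <- function(re, coords = c("q", "e_rg"), t_target, tol = 1e-7, max_iter = 1e5) {
  coords <- match.arg(coords)
  energy <- re$energy
  temperatures <- re$temperatures
  beta <- 1 / temperatures
  beta_t <- 1 / t_target
  shifts <- wham_shifts(energy, temperatures, tol = tol, max_iter = max_iter)
  logw_level <- wham_level_logw(shifts, beta, beta_t, rep(nrow(energy), ncol(energy)))
  lev <- shifts$levels
  sample_logw <- matrix(logw_level[match(as.vector(energy), lev)], nrow = nrow(energy))
  if (coords == "q") {
    qv <- as.vector(re$q)
    wv <- as.vector(sample_logw)
    qs <- sort(unique(qv))
    logdens <- vapply(qs, function(q) logsumexp(wv[qv == q]), numeric(1))
    f <- -t_target * logdens
    f <- f - min(f)
    out <- data.frame(q = qs, f = f,
                      weight = exp(logdens - logsumexp(logdens)))
    class(out) <- c("free_energy_profile", "data.frame")
    attr(out, "t_target") <- t_target
    attr(out, "shifts") <- shifts
    return(out)
  }
  rgv <- as.vector(re$rg)
  ev <- as.vector(energy)
  wv <- as.vector(sample_logw)
  rg_breaks <- seq(floor(min(rgv) / 0.5) * 0.5, ceiling(max(rgv) / 0.5) * 0.5, by = 0.5)
  rg_bin <- findInterval(rgv, rg_breaks, rightmost.closed = TRUE)
  fmat <- matrix(NA_real_, length(lev), length(rg_breaks) - 1L)
  for (li in seq_along(lev)) {
    sel <- ev == lev[li]
    if (!any(sel)) next
    for (bi in unique(rg_bin[sel])) {
      fmat[li, bi] <- -t_target * logsumexp(wv[sel & rg_bin == bi])
    }
  }
  fmat <- fmat - min(fmat, na.rm = TRUE)
  out <- list(energy_levels = lev, rg_breaks = rg_breaks, f = fmat)
  class(out) <- "free_energy_surface"
  attr(out, "t_target") <- t_target
  attr(out, "shifts") <- shifts
  out
}
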