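# two-level system (E = 0 or -g): exact Boltzmann sampling gives closed-form
# heat capacity Cv(T) = (g^2/T^2) p (1 - p) with p = occupancy of -g.
two_level_samples <- function(g, temps, n) {
  p <- exp(g / temps) / (1 + exp(g / temps))
  sapply(seq_along(temps), function(i) -g * (runif(n) < p[i]))
}
two_level_cv <- function(g, temps) {
  p <- exp(g / temps) / (1 + exp(g / temps))
  g^2 * p * (1 - p) / temps^2
}

test_that("heat capacity from fluctuations matches the two-level closed form", {
  expect_equal(heat_capacity(matrix(-5, 100, 3), c(0.5, 1, 2))$cv, c(0, 0, 0))
  set.seed(8)
  g <- 3
  temps <- seq(0.5, 3, length.out = 12)
  E <- two_level_samples(g, temps, n = 4e4)
  cv <- heat_capacity(E, temps)
  exact <- two_level_cv(g, temps)
  expect_lt(max(abs(cv$cv - exact)), 0.1)      # Monte Carlo error at n = 4e4
  # order permutation cannot matter
  cv2 <- heat_capacity(E[sample(nrow(E)), ], temps)
  expect_equal(cv2$cv, cv$cv)
})

test_that("melting temperature is the Cv argmax with ties resolved low", {
  curve <- data.frame(temperature = c(0.5, 0.7, 0.9), cv = c(1, 5, 2))
  expect_equal(estimate_tm(curve), 0.7)
  tied <- data.frame(temperature = c(0.5, 0.7, 0.9), cv = c(1, 5, 5))
  expect_message(tm <- estimate_tm(tied), "tied")
  expect_equal(tm, 0.7)
  # two-level system: Cv peak within 10% of the analytic peak location
  g <- 3
  temps <- exp(seq(log(0.3), log(4), length.out = 60))
  exact <- two_level_cv(g, temps)
  t_star <- temps[which.max(exact)]
  set.seed(9)
  E <- two_level_samples(g, temps, n = 4e4)
  tm_hat <- estimate_tm(heat_capacity(E, temps))
  expect_lt(abs(tm_hat - t_star) / t_star, 0.1)
})

test_that("WHAM reduces to the direct histogram estimate for one temperature", {
  set.seed(14)
  n <- 4000
  E <- matrix(sample(c(0, -1, -2, -3), n, TRUE, prob = c(0.4, 0.3, 0.2, 0.1)))
  q <- matrix((-E) / 3)
  re <- structure(list(energy = E, q = q,
                       rg = matrix(5.0, n, 1), temperatures = 1.0),
                  class = "replica_exchange")
  fq <- wham(re, "q", t_target = 1.0)
  direct <- -1.0 * log(as.vector(table(q) / n))
  direct <- direct - min(direct)
  expect_equal(fq$f, direct, tolerance = 1e-10)
})

test_that("WHAM reweighting reproduces per-temperature sample means", {
  K <- protein_k()
  grid <- build_temperature_grid(0.6, 1.3, 8)
  re <- run_replica_exchange(K, grid, sweep_steps = 3000, n_sweeps = 300,
                             seed = 17)
  shifts <- knotfold:::wham_shifts(re$energy, re$temperatures)
  # reweight to a grid temperature: <E> must match that column's mean
  for (ti in c(2L, 5L)) {
    lw <- knotfold:::wham_level_logw(shifts, 1 / re$temperatures,
                                     1 / re$temperatures[ti],
                                     rep(nrow(re$energy), length(grid)))
    w <- exp(lw - max(lw))
    lev <- shifts$levels
    h <- vapply(lev, function(l) sum(re$energy == l), numeric(1))
    est <- sum(lev * h * w) / sum(h * w)
    direct <- mean(re$energy[, ti])
    se <- sd(re$energy[, ti]) / sqrt(25)   # generous: samples are correlated
    expect_lt(abs(est - direct), 4 * se + 0.3)
  }
  # shifts are converged: doubling the iteration cap changes nothing
  shifts2 <- knotfold:::wham_shifts(re$energy, re$temperatures, max_iter = 2e5)
  expect_equal(shifts$f, shifts2$f, tolerance = 1e-6)
})

test_that("WHAM diagnoses non-overlapping histograms", {
  E <- cbind(rep(c(-10, -11), 50), rep(c(0, -1), 50))
  re <- structure(list(energy = E, q = E / -20, rg = E * 0 + 3,
                       temperatures = c(0.5, 2)), class = "replica_exchange")
  expect_error(wham(re, "q", t_target = 1), "do not overlap")
})

test_that("free-energy surfaces are min-shifted with empty cells flagged", {
  K <- protein_k()
  grid <- build_temperature_grid(0.6, 1.3, 6)
  re <- run_replica_exchange(K, grid, sweep_steps = 2000, n_sweeps = 150,
                             seed = 23)
  fs <- wham(re, "e_rg", t_target = 1.0)
  expect_equal(min(fs$f, na.rm = TRUE), 0)
  expect_true(any(is.na(fs$f)))            # unvisited cells are NA, not zero
  fq <- wham(re, "q", t_target = 1.0)
  expect_equal(min(fq$f), 0)
  expect_true(all(fq$q %in% ((0:40) / 40)))
})
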