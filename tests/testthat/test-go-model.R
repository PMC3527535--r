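test_that("Go energy is epsilon times the number of formed native contacts", {
  u4 <- lattice_conformation(rbind(c(0,0,0), c(1,0,0), c(1,1,0), c(0,1,0)))
  native <- compute_contacts(u4)
  model <- go_model(native)
  expect_equal(go_energy(u4, model), -1)
  expect_equal(go_energy(straight_rod(4), model), 0)
  expect_equal(go_energy(u4, go_model(native, epsilon = -2.5)), -2.5)
  expect_error(go_model(native, epsilon = 1), "negative")
  # arbitrary conformations: energy equals -|formed intersect native| by the oracle
  set.seed(1)
  for (k in 1:15) {
    conf <- random_unfolded(10, seed = k)
    pairs <- oracle_contacts(unclass(conf))
    nat <- contact_map(rbind(c(1, 4), c(2, 7)))
    formed_native <- 0
    if (nrow(pairs) > 0)
      formed_native <- sum((pairs[, 1] == 1 & pairs[, 2] == 4) |
                           (pairs[, 1] == 2 & pairs[, 2] == 7))
    expect_equal(go_energy(conf, go_model(nat)), -formed_native)
  }
})

test_that("Metropolis acceptance has the right limits and empirical rate", {
  expect_true(all(metropolis_accept(-3, 1, n = 100)))
  expect_true(all(metropolis_accept(0, 1, n = 100)))
  expect_true(all(metropolis_accept(1, 1e6, n = 100)))
  expect_error(metropolis_accept(1, 0), "positive")
  set.seed(11)
  n <- 1e5
  acc <- mean(metropolis_accept(2, 1, n = n))
  p <- exp(-2)
  se <- sqrt(p * (1 - p) / n)
  expect_lt(abs(acc - p), 3 * se)
})

test_that("incremental contact bookkeeping survives a debug-checked run", {
  u4 <- lattice_conformation(rbind(c(0,0,0), c(1,0,0), c(1,1,0), c(0,1,0)))
  nat <- list(conformation = u4, native_map = compute_contacts(u4))
  # debug_checks re-derives the tallies from scratch at every record and
  # errors on divergence; a clean long run is the assertion
  run <- run_folding(nat, temperature = 0.8, max_steps = 2e5,
                     record_interval = 1e3, seed = 6, stop_at_fold = FALSE,
                     debug_checks = TRUE)
  expect_equal(nrow(run$trajectory), 201L)
  # the Go identity E = -Q * n_native holds in every record
  expect_equal(run$trajectory$energy, -run$trajectory$Q * nrow(nat$native_map))
})
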