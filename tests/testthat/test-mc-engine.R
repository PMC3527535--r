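toy_native <- function() {
  u4 <- lattice_conformation(rbind(c(0,0,0), c(1,0,0), c(1,1,0), c(0,1,0)))
  list(conformation = u4, native_map = compute_contacts(u4))
}

test_that("runs are bit-reproducible for identical (native, params, seed)", {
  nat <- toy_native()
  a <- run_folding(nat, 0.7, 5e4, record_interval = 1e3, seed = 12,
                   stop_at_fold = FALSE, snapshot_interval = 5e3)
  b <- run_folding(nat, 0.7, 5e4, record_interval = 1e3, seed = 12,
                   stop_at_fold = FALSE, snapshot_interval = 5e3)
  expect_identical(a$trajectory, b$trajectory)
  expect_identical(lapply(a$snapshots, unclass), lapply(b$snapshots, unclass))
  c <- run_folding(nat, 0.7, 5e4, record_interval = 1e3, seed = 13,
                   stop_at_fold = FALSE)
  expect_false(identical(a$trajectory, c$trajectory))
})

test_that("first passage semantics: native start folds at time zero", {
  nat <- toy_native()
  r <- run_folding(nat, 1.0, 1e4, start = nat$conformation, seed = 1)
  expect_true(r$folded)
  expect_identical(r$fpt, 0)
})

test_that("the bulk 4-mer toy folds in every seeded run at low temperature", {
  nat <- toy_native()
  for (s in 1:50) {
    r <- run_folding(nat, 0.5, 1e6, record_interval = 1e6, seed = s)
    expect_true(r$folded)
    expect_true(is.finite(r$fpt))
  }
})

test_that("unfolded starts respect the Q ceiling and the tether geometry", {
  K <- protein_k()
  for (s in 1:5) {
    conf <- random_unfolded(41, native = K$native_map, max_q = 0.2, seed = s)
    expect_lte(fraction_native(conf, K$native_map), 0.2)
  }
  setup <- folding_setup("plane_tether", anchored_bead = 1L)
  conf <- random_unfolded(41, setup, K$native_map, seed = 3)
  expect_identical(unclass(conf)[1, ], c(x = 0L, y = 0L, z = 1L))
  expect_true(all(unclass(conf)[, 3] >= 1L))
  setupN <- folding_setup("plane_tether", anchored_bead = 41L)
  confN <- random_unfolded(41, setupN, K$native_map, seed = 3)
  expect_identical(unclass(confN)[41, ], c(x = 0L, y = 0L, z = 1L))
})

test_that("plane tethering holds through whole trajectories", {
  K <- protein_k()
  setup <- folding_setup("plane_tether", anchored_bead = 1L)
  r <- run_folding(K, 1.0, 2e5, record_interval = 1e4, snapshot_interval = 5e3,
                   setup = setup, seed = 21, stop_at_fold = FALSE)
  expect_gt(length(r$snapshots), 10)
  for (s in r$snapshots) {
    m <- unclass(s)
    expect_identical(m[1, ], c(x = 0L, y = 0L, z = 1L))
    expect_true(all(m[, 3] >= 1L))
  }
  expect_identical(unclass(r$final)[1, ], c(x = 0L, y = 0L, z = 1L))
})

test_that("temperature grids are geometric and bracket their bounds", {
  expect_equal(build_temperature_grid(0.5, 1.4, 2), c(0.5, 1.4))
  g <- build_temperature_grid(0.4, 1.6, 40)
  expect_identical(length(g), 40L)
  ratios <- g[-1] / g[-length(g)]
  expect_lt(diff(range(ratios)), 1e-12)
  expect_error(build_temperature_grid(1.4, 0.5), "t_low")
})

test_that("replica exchange swaps freely on a dense grid and orders energies", {
  K <- protein_k()
  grid <- build_temperature_grid(0.55, 1.3, 8)
  re <- run_replica_exchange(K, grid, sweep_steps = 2000, n_sweeps = 150,
                             seed = 5)
  expect_identical(dim(re$energy), c(120L, 8L))
  # mean energy is non-decreasing in temperature (thermodynamic consistency)
  me <- colMeans(re$energy)
  expect_true(all(diff(me) > -1.0))   # allow small sampling noise
  expect_gt(mean(re$swap_acceptance), 0.5)
  # two identical temperatures always exchange
  re2 <- run_replica_exchange(K, c(1, 1 + 1e-12), sweep_steps = 500,
                              n_sweeps = 40, seed = 2)
  expect_equal(mean(re2$swap_acceptance), 1.0)
})

test_that("a dense temperature grid keeps replica exchanges near-certain", {
  K <- protein_k()
  grid <- build_temperature_grid(0.5, 0.95, 56)
  re <- run_replica_exchange(K, grid, sweep_steps = 4000, n_sweeps = 300,
                             seed = 3)
  expect_gte(mean(re$swap_acceptance), 0.95)
})
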