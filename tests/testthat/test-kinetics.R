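fake_runs <- function(fpts, budget, censored = 0L) {
  runs <- lapply(fpts, function(t)
    list(folded = TRUE, fpt = t,
         params = list(max_steps = budget, temperature = 1)))
  cens <- lapply(seq_len(censored), function(i)
    list(folded = FALSE, fpt = NA_real_,
         params = list(max_steps = budget, temperature = 1)))
  c(runs, cens)
}

test_that("foldicity is the folded fraction and degenerate fits are refused", {
  res <- collect_fpts(fake_runs(1:10 * 100, budget = 1e4))
  expect_equal(res$foldicity, 1.0)
  expect_identical(res$n_folded, 10L)
  res2 <- collect_fpts(fake_runs(1:9 * 100, budget = 1e4, censored = 11L))
  expect_equal(res2$foldicity, 0.45)
  res0 <- collect_fpts(fake_runs(numeric(0), budget = 1e4, censored = 5L))
  expect_equal(res0$foldicity, 0)
  expect_error(fit_rate(res0), "refused")
  mixed <- c(fake_runs(1:5, 1e4), fake_runs(6:9, 2e4))
  expect_error(collect_fpts(mixed), "share parameters")
})

test_that("the survival curve counts censored runs as unfolded through the budget", {
  res <- collect_fpts(fake_runs(c(10, 20, 30), budget = 100, censored = 1L))
  sc <- survival_curve(res, times = c(5, 10, 25, 100))
  expect_equal(sc$p_unfolded, c(1, 0.75, 0.5, 0.25))
})

test_that("exponential rates are recovered from synthetic first-passage times", {
  set.seed(4)
  k_true <- 1e-6
  fpts <- rexp(2000, rate = k_true)
  res <- collect_fpts(fake_runs(fpts, budget = max(fpts) * 1.01))
  fit <- fit_rate(res)
  expect_lt(abs(fit$rate - k_true) / k_true, 0.05)
  expect_gt(fit$fit$r_squared, 0.99)
  # ~30% censoring at budget = 1.2/k
  budget <- 1.2 / k_true
  folded <- fpts[fpts <= budget]
  res2 <- collect_fpts(fake_runs(folded, budget = budget,
                                 censored = sum(fpts > budget)))
  fit2 <- fit_rate(res2)
  expect_lt(abs(fit2$rate - k_true) / k_true, 0.15)
})

test_that("rates are scale-equivariant and order-invariant", {
  set.seed(6)
  fpts <- rexp(500, rate = 1e-5)
  budget <- max(fpts) * 1.01
  k1 <- fit_rate(collect_fpts(fake_runs(fpts, budget)))$rate
  k2 <- fit_rate(collect_fpts(fake_runs(2 * fpts, 2 * budget)))$rate
  expect_equal(k2, k1 / 2, tolerance = 1e-12)
  k3 <- fit_rate(collect_fpts(fake_runs(sample(fpts), budget)))$rate
  expect_equal(k3, k1, tolerance = 1e-12)
})
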