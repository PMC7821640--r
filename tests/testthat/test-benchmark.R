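test_that("FDR selection matches the hand step-up oracle", {
  # the step-up rule itself, on a printed list: 0.001, 0.02, 0.03 rejected
  expect_equal(bh_stepup_oracle(c(0.001, 0.02, 0.03, 0.5), q = 0.05), 1:3)
  expect_equal(bh_stepup_oracle(rep(1, 6), q = 0.05), integer(0))

  # the selector agrees with the oracle applied to the same per-feature tests
  for (s in 1:5) {
    sim <- simulate_layers(n = 20, seed = 900 + s, p_noise = 60)
    ds <- mean_center(sim$X, sim$Y)
    pv <- correlation_filter(ds, alpha_f = 1)$p_value
    expect_equal(fdr_select(ds, q = 0.05), bh_stepup_oracle(pv, 0.05))
    expect_equal(fdr_select(ds, q = 0.01), bh_stepup_oracle(pv, 0.01))
  }
})

test_that("lasso selection obeys the soft-threshold rule on orthogonal designs", {
  # columns mutually orthogonal, mean zero, norm sqrt(n)
  X <- cbind(c(1, 1, -1, -1), c(1, -1, 1, -1), c(1, -1, -1, 1))
  y <- c(2.0, 0.4, -0.6, -1.8)
  ds <- mean_center(X, y)
  z <- drop(crossprod(ds$X, ds$Y)) / nrow(X)  # per-column score X'y/n
  for (lam in c(0.05, 0.3, 0.8)) {
    expect_equal(lasso_select(ds, lambda = lam, standardize = FALSE),
                 which(abs(z) > lam))
  }
})

test_that("lasso shrinkage limits behave as expected", {
  set.seed(31)
  X <- matrix(rnorm(40 * 8), 40, 8)
  y <- drop(X %*% c(3, -2, rep(0, 6))) + rnorm(40, sd = 0.1)
  ds <- mean_center(X, y)
  expect_equal(lasso_select(ds, lambda = 1e4), integer(0))
  expect_true(all(c(1, 2) %in% lasso_select(ds, lambda = 0.05)))

  # single predictor perfectly correlated with the response
  x1 <- matrix(rnorm(20), 20, 1)
  ds1 <- mean_center(x1, drop(x1) * 2)
  expect_equal(lasso_select(ds1, lambda = 0.01), 1L)
})

test_that("q_squared follows the uncentered formula", {
  expect_equal(q_squared(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(q_squared(c(1, 2, 3), c(0, 0, 0)), 0)
  expect_equal(q_squared(c(3, 4), c(3, 0)), 0.36)
  expect_error(q_squared(c(0, 0), c(1, 1)), "undefined")
})

test_that("precision is the selected-overlap fraction, missing when empty", {
  expect_equal(precision_metric(c(1, 2), c(1, 2, 3)), 1)
  expect_equal(precision_metric(c(1, 9), 1), 0.5)
  expect_true(is.na(precision_metric(integer(0), 1:3)))
})

test_that("train/test evaluation returns finite metrics and honours truth", {
  sim <- simulate_layers(n = 30, seed = 33, p_noise = 70)
  ev <- train_test_evaluate(
    sim$X, sim$Y,
    selector = function(X, y) fdr_select(mean_center(X, y), q = 0.05),
    repeats = 3, truth = sim$truth, seed = 1
  )
  expect_true(all(is.finite(c(ev$summary$mse, ev$summary$q2, ev$summary$n_selected))))
  expect_true(ev$summary$precision >= 0 && ev$summary$precision <= 1)
  expect_equal(nrow(ev$repeats), 3L)

  # a selector that never selects falls back to the intercept-only model
  ev0 <- train_test_evaluate(sim$X, sim$Y, selector = function(X, y) integer(0),
                             repeats = 2, seed = 2)
  expect_true(all(is.finite(ev0$summary$mse)))
  expect_true(is.na(ev0$summary$precision) || is.nan(ev0$summary$precision))
})

test_that("benchmark smoke run produces well-formed bounded counts", {
  bench <- run_benchmark(R = 2, methods = c("oplsr_b", "fdr"), levels = 0.05,
                         cfg = permutation_config(B = 19, subset_fraction = 1),
                         n = 20, seed = 4)
  counts <- tidyr::pivot_wider(bench$counts[, c("method", "level", "layer", "mean_count")],
                               names_from = "layer", values_from = "mean_count")
  expect_equal(nrow(counts), 2L)
  expect_true(all(counts$layer1 <= 30))
  expect_true(all(counts$layer2 <= 90))
  expect_true(all(counts$layer3 <= 270))
  expect_true(all(counts$noise <= 610))
  expect_true(all(bench$counts$mean_count >= 0))
  # variance decomposition rows averaged over replicates are present
  expect_true(all(c("X_orth", "X_osc", "Y") %in% bench$variance$part))
})
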