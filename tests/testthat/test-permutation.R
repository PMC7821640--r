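test_that("permutation p-values follow the (count + 1) / (N + 1) rule", {
  expect_equal(permutation_pvalues(2, list(c(-1, 0, 1, 3))), 0.4)
  # observed zero can never be extreme
  expect_equal(permutation_pvalues(0, list(rnorm(50))), 1)
  # all null draws strictly smaller in magnitude: smallest attainable p
  expect_equal(permutation_pvalues(5, list(runif(999, -1, 1))), 1 / 1000)
})

test_that("null intervals are linear-interpolation percentiles", {
  # hand computation, linear interpolation at the 20th/80th percentile of
  # the ordered samples 1..20: h = (20-1)p + 1 gives 4.8 and 16.2
  ci <- permutation_intervals(list(sample(1:20)), alpha_pm = 0.4)
  expect_equal(ci$ci_low, 4.8)
  expect_equal(ci$ci_high, 16.2)

  all_zero <- permutation_intervals(list(rep(0, 30)), alpha_pm = 0.05)
  expect_equal(all_zero$ci_low, 0)
  expect_equal(all_zero$ci_high, 0)

  expect_error(permutation_intervals(list(rnorm(5))), "at least 19")
})

test_that("subset fraction one permutes everything in exactly B iterations", {
  d <- rand_centered(10, 6, seed = 80)
  osc <- fit_osc(d$X, Y = d$y)
  set.seed(1)
  nul <- permutation_null(osc$X_osc, d$y, osc,
                          permutation_config(B = 25, subset_fraction = 1))
  expect_equal(nul$n_iterations, 25L)
  expect_true(all(lengths(nul$samples) == 25L))
})

test_that("every candidate accumulates at least B null samples under subsetting", {
  d <- rand_centered(12, 20, seed = 81)
  osc <- fit_osc(d$X, Y = d$y)
  set.seed(2)
  nul <- permutation_null(osc$X_osc, d$y, osc,
                          permutation_config(B = 40, subset_fraction = 0.3))
  expect_true(all(lengths(nul$samples) >= 40L))
})

test_that("configuration bounds are enforced", {
  expect_error(permutation_config(B = 10), "at least 19")
  expect_error(permutation_config(subset_fraction = 0), "subset_fraction")
  expect_error(permutation_config(subset_fraction = 1.2), "subset_fraction")
  expect_error(permutation_config(alpha_pm = 0), "alpha_pm")
})

test_that("identical seed and configuration reproduce the selection bit for bit", {
  sim <- simulate_layers(n = 20, seed = 5, p_noise = 60)
  cfg <- permutation_config(B = 49)
  f1 <- oplsr(sim$X, sim$Y, alpha_f = 0.10, cfg = cfg, seed = 99)
  f2 <- oplsr(sim$X, sim$Y, alpha_f = 0.10, cfg = cfg, seed = 99)
  expect_identical(f1$results, f2$results)
  expect_identical(f1$selected, f2$selected)
})

test_that("selection shrinks as alpha_pm decreases and under Bonferroni", {
  sim <- simulate_layers(n = 24, seed = 6, p_noise = 80)
  sel_at <- function(alpha, bonf = FALSE) {
    oplsr(sim$X, sim$Y, alpha_f = 0.2,
          cfg = permutation_config(B = 199, alpha_pm = alpha, bonferroni = bonf),
          seed = 7)$selected
  }
  s10 <- sel_at(0.10)
  s05 <- sel_at(0.05)
  s01 <- sel_at(0.01)
  sbf <- sel_at(0.05, bonf = TRUE)
  expect_true(all(s05 %in% s10))
  expect_true(all(s01 %in% s05))
  expect_true(all(sbf %in% s05))
  expect_lte(length(sbf), length(s05))
})

test_that("selected variables lie outside their null interval, and selection
           respects the filter", {
  sim <- simulate_layers(n = 30, seed = 8, p_noise = 100)
  fit <- oplsr(sim$X, sim$Y, alpha_f = 0.05,
               cfg = permutation_config(B = 199), seed = 11)
  res <- fit$results
  expect_true(all(fit$selected %in% fit$filtered_in))
  expect_true(all(res$p_value >= 1 / (199 + 1)))
  sel <- res[res$selected, ]
  expect_true(all(sel$p_value < 0.05))
  # the percentile interval and the two-tailed absolute-value p-value are
  # built differently, so they may disagree on borderline asymmetric nulls;
  # concordance should still be near-total
  outside <- sel$beta < sel$ci_low | sel$beta > sel$ci_high
  expect_gte(mean(outside), 0.95)
  # filtered-out variables report zero coefficient and p = 1
  out <- res[!res$filtered_in, ]
  expect_true(all(out$beta == 0))
  expect_true(all(out$p_value == 1))
})

test_that("an impossibly strict filter raises a no-candidates error", {
  set.seed(12)
  X <- matrix(rnorm(40 * 30), 40, 30)
  y <- rnorm(40)
  expect_error(oplsr(X, y, alpha_f = 1e-12), "pass the correlation")
})
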