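test_that("first PLS weight is the normalised covariance direction", {
  d <- rand_centered(12, 8, seed = 50)
  f <- fit_opls(d$X, d$y, A = 1)
  c0 <- drop(crossprod(d$X, d$y))
  w <- c0 / sqrt(sum(c0^2))
  dir <- f$weights[, 1] / sqrt(sum(f$weights[, 1]^2))
  expect_lt(min(max(abs(dir - w)), max(abs(dir + w))), 1e-10)
})

test_that("scores are orthonormal and match the NIPALS oracle up to sign", {
  d <- rand_centered(10, 6, seed = 51)
  f <- fit_opls(d$X, d$y, A = 2)
  expect_lt(max(abs(crossprod(f$scores) - diag(2))), 1e-10)
  expect_lt(max_score_diff(f$scores, nipals_pls1_oracle(d$X, d$y, 2)), 1e-8)

  # weights reproduce the scores against the undeflated matrix
  expect_lt(max(abs(d$X %*% f$weights - f$scores)), 1e-10)
})

test_that("regression vectors satisfy the X beta_b = X_osc beta_a identity", {
  for (s in 1:20) {
    set.seed(600 + s)
    n <- sample(6:16, 1)
    p <- sample(4:30, 1)
    d <- rand_centered(n, p, seed = 600 + s)
    osc <- fit_osc(d$X, Y = d$y)
    pls <- fit_opls(osc$X_osc, d$y, A = 1)
    co <- opls_coefficients(osc, pls)
    lhs <- d$X %*% co$beta_b
    rhs <- osc$X_osc %*% co$beta_a
    expect_lt(max(abs(lhs - rhs)) / max(1e-12, max(abs(rhs))), 1e-8)
    # fitted values follow the latent-score chain t t' y
    chain <- pls$scores %*% crossprod(pls$scores, d$y)
    expect_lt(max(abs(rhs - chain)), 1e-8)
  }
})

test_that("beta_b equals beta_a when no orthogonal structure is removed", {
  set.seed(61)
  y <- rnorm(10); y <- y - mean(y)
  X <- outer(y, c(2, -1, 0.5)) # columns proportional to y: OSC removes nothing
  osc <- fit_osc(X, Y = y)
  pls <- fit_opls(osc$X_osc, y, A = 1)
  co <- opls_coefficients(osc, pls)
  expect_equal(co$beta_a, co$beta_b)
})

test_that("predictions center new data with training means", {
  set.seed(62)
  X <- matrix(rnorm(60), 12, 5) + 5
  y <- rnorm(12) + 2
  ds <- mean_center(X, y)
  osc <- fit_osc(ds)
  pls <- fit_opls(osc$X_osc, ds$Y, A = 1)
  co <- opls_coefficients(osc, pls)

  # on the training data, prediction equals the latent fit plus the mean
  chain <- drop(pls$scores %*% crossprod(pls$scores, ds$Y)) + ds$y_center
  expect_equal(predict_response(co$beta_b, X, ds), chain, tolerance = 1e-8)

  # zero coefficients predict the training mean
  expect_equal(predict_response(rep(0, 5), X, ds), rep(ds$y_center, 12))

  # holdout rows match the brute-force computation
  Xn <- matrix(rnorm(20), 4, 5)
  brute <- drop(sweep(Xn, 2, ds$x_center, "-") %*% co$beta_b) + ds$y_center
  expect_equal(predict_response(co$beta_b, Xn, ds), brute, tolerance = 1e-12)
})

test_that("a perfectly y-aligned rank-1 matrix is explained by one component", {
  set.seed(63)
  y <- rnorm(9); y <- y - mean(y)
  X <- outer(y, c(1, 2, 3))
  osc <- fit_osc(X, Y = y)
  pls <- fit_opls(osc$X_osc, y, A = 1)
  vt <- variance_table(osc, pls)
  expect_equal(vt$fraction[vt$part == "X_osc" & vt$component == "PLS1"], 1,
               tolerance = 1e-8)
  expect_equal(vt$fraction[vt$part == "Y" & vt$component == "PLS1"], 1,
               tolerance = 1e-8)
})

test_that("variance fractions close to one with explicit residuals", {
  d <- rand_centered(8, 4, seed = 64)
  osc <- fit_osc(d$X, Y = d$y)
  pls <- fit_opls(osc$X_osc, d$y, A = 2)
  vt <- variance_table(osc, pls)

  # X: removed components plus the corrected remainder account for all of X
  x_orth <- sum(vt$fraction[vt$part == "X_orth"])
  expect_equal(x_orth + osc$frac_var_osc, 1, tolerance = 1e-8)

  # X_osc: per-component fractions plus residual sum to one, and the
  # residual matches an explicit recomputation
  xo <- vt[vt$part == "X_osc" & vt$component != "OSC", ]
  expect_equal(sum(xo$fraction), 1, tolerance = 1e-8)
  resid_explicit <- sum((osc$X_osc - pls$scores %*% crossprod(pls$scores, osc$X_osc))^2) /
    sum(osc$X_osc^2)
  expect_equal(xo$fraction[xo$component == "residual"], resid_explicit,
               tolerance = 1e-8)

  # Y: fractions plus residual sum to one
  expect_equal(sum(vt$fraction[vt$part == "Y"]), 1, tolerance = 1e-8)
})

test_that("with all components and no OSC, PLS reaches the least-squares fit", {
  d <- rand_centered(9, 5, seed = 65)
  A <- qr(d$X)$rank
  pls <- fit_opls(d$X, d$y, A = A)
  fitted_pls <- drop(pls$scores %*% crossprod(pls$scores, d$y))
  fitted_ls <- drop(d$X %*% minimum_norm_ls_oracle(d$X, d$y))
  expect_equal(fitted_pls, fitted_ls, tolerance = 1e-6)
})

test_that("rank and signal errors are raised", {
  d <- rand_centered(6, 3, seed = 66)
  expect_error(fit_opls(d$X, d$y, A = 10), "exceeds|rank")
  set.seed(67)
  X <- matrix(rnorm(30), 10, 3)
  y_orth <- residuals(lm(rnorm(10) ~ X))  # response orthogonal to all columns
  expect_error(fit_opls(scale(X, scale = FALSE), y_orth, A = 1), "covariance|signal")
})
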