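#' Fit PLS with orthonormal scores on an OSC-corrected matrix
#'
#' PLS1 with a univariate response. The first weight is the leading left
#' singular vector of the covariance \eqn{(X^{OSC})^\top Y}; its score is
#' normalised to unit Euclidean length (the weight rescaled accordingly), so
#' the score matrix `t` satisfies \eqn{t^\top t = I} and the latent
#' regression estimate reduces to \eqn{\hat\beta = t^\top Y}. Later
#' components are extracted after deflating X by the projection onto the
#' previously extracted scores (`X <- X - t t' X`; the response is never
#' deflated), which keeps the scores mutually orthonormal. Weights are
#' re-expressed against the *undeflated* matrix, so `t = X_osc %*% r` holds
#' for the returned weight matrix, and the loadings are computed against the
#' undeflated inputs: `P = t(X_osc) %*% t`, `Q = t(Y) %*% t`.
#'
#' @param X_osc Centered (typically OSC-corrected) numeric matrix, n x p.
#' @param Y Centered numeric response of length n.
#' @param A Number of predictive components (default 1). Must not exceed the
#'   rank of `X_osc`.
#' @return An object of class `opls_model`: list with `scores` (n x A,
#'   orthonormal), `weights` (p x A, `r`), `loadings_x` (p x A, `P`),
#'   `loadings_y` (length A, `Q`), `A`, `var_x_per_comp`, `var_y_per_comp`,
#'   `ss_x`, `ss_y`.
#' @export
fit_opls <- function(X_osc, Y, A = 1L) {
  X_osc <- as_numeric_matrix(X_osc)
  y <- as.numeric(Y)
  n <- nrow(X_osc)
  p <- ncol(X_osc)
  A <- as.integer(A)
  if (A < 1L) stop("`A` must be at least 1", call. = FALSE)
  if (nrow(X_osc) != length(y)) stop("dimension mismatch between `X_osc` and `Y`", call. = FALSE)

  core <- pls1_core(X_osc, y, A)
  Tm <- core$scores
  R <- core$weights
  P <- crossprod(X_osc, Tm)
  Q <- drop(crossprod(y, Tm))
  ss_x <- sum(X_osc^2)
  ss_y <- sum(y^2)
  structure(
    list(
      scores = Tm, weights = R, loadings_x = P, loadings_y = Q, A = A,
      var_x_per_comp = colSums(P^2) / ss_x,
      var_y_per_comp = Q^2 / ss_y,
      ss_x = ss_x, ss_y = ss_y
    ),
    class = "opls_model"
  )
}

# Lean PLS1 with orthonormal scores; weights expressed against the
# undeflated X so that scores == X %*% weights. Used both for model fitting
# and inside the permutation loop, where it must be cheap.
pls1_core <- function(X, y, A) {
  n <- nrow(X)
  p <- ncol(X)
  Tm <- matrix(0, n, A)
  R <- matrix(0, p, A)
  Xd <- X
  tol <- sqrt(.Machine$double.eps)
  for (j in seq_len(A)) {
    cvec <- drop(crossprod(Xd, y))
    nc <- sqrt(sum(cvec^2))
    if (nc <= tol * max(1, sqrt(sum(Xd^2)) * sqrt(sum(y^2)))) {
      if (j == 1L) stop("zero covariance between `X_osc` and `Y`; no signal to model", call. = FALSE)
      stop("`A` = ", A, " exceeds the number of extractable components (", j - 1L, ")", call. = FALSE)
    }
    w <- cvec / nc
    t_raw <- drop(Xd %*% w)
    nt <- sqrt(sum(t_raw^2))
    if (nt <= tol) {
      stop("`A` = ", A, " exceeds the rank of `X_osc`", call. = FALSE)
    }
    # weight against the undeflated X: t_raw = X (w - sum_i r_i * t_i' X w)
    r <- w
    if (j > 1L) {
      prev <- seq_len(j - 1L)
      a <- drop(crossprod(Tm[, prev, drop = FALSE], X %*% w))
      r <- w - R[, prev, drop = FALSE] %*% a
    }
    Tm[, j] <- t_raw / nt
    R[, j] <- r / nt
    # deterministic sign: largest-magnitude weight entry positive
    i_max <- which.max(abs(R[, j]))
    if (R[i_max, j] < 0) {
      R[, j] <- -R[, j]
      Tm[, j] <- -Tm[, j]
    }
    if (j < A) Xd <- Xd - tcrossprod(Tm[, j]) %*% Xd
  }
  list(scores = Tm, weights = R)
}

#' @export
print.opls_model <- function(x, ...) {
  cat("<opls_model> ", x$A, " predictive component(s); Y variance captured: ",
      paste(sprintf("%.3f", x$var_y_per_comp), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' OPLS regression vectors against the corrected and the original X
#'
#' Builds the two regression vectors of an OSC + PLS fit:
#' \deqn{\hat\beta_{OPLSa} = r Q^\top} expressed against the corrected
#' matrix \eqn{X^{OSC}}, and
#' \deqn{\hat\beta_{OPLSb} = (I - r_{osc} p_{osc}^\top)\, \hat\beta_{OPLSa}}
#' expressed against the original `X`, so that
#' \eqn{X \hat\beta_{OPLSb} = X^{OSC} \hat\beta_{OPLSa}} identically. The
#' rank-one correction is applied as `beta_a - r_osc (p_osc' beta_a)`; the
#' p x p matrix is never formed. With zero OSC components the two vectors
#' coincide.
#'
#' `beta_b` weighs each variable's total contribution (orthogonal plus
#' predictive directions) and is the recommended vector for selection;
#' `beta_a` is kept for comparison.
#'
#' @param osc An `osc_model`.
#' @param pls An `opls_model` fitted on `osc$X_osc`.
#' @return A tibble with columns `index`, `beta_a`, `beta_b`.
#' @export
opls_coefficients <- function(osc, pls) {
  stopifnot(inherits(osc, "osc_model"), inherits(pls, "opls_model"))
  beta_a <- drop(pls$weights %*% pls$loadings_y)
  if (osc$n_components > 0L) {
    if (nrow(osc$r_osc) != length(beta_a)) {
      stop("OSC and PLS models have incompatible dimensions", call. = FALSE)
    }
    beta_b <- beta_a - drop(osc$r_osc %*% crossprod(osc$p_osc, beta_a))
  } else {
    beta_b <- beta_a
  }
  tibble::tibble(index = seq_along(beta_a), beta_a = beta_a, beta_b = beta_b)
}

#' Predict a response from a regression vector
#'
#' Centers `X_new` with the training column means (and scales, when the
#' training data were scaled), applies the regression vector, and adds back
#' the training response mean: `(X_new - means) %*% beta + mean_Y`.
#'
#' @param beta Length-p regression vector (`beta_b` for raw spectra;
#'   `beta_a` for OSC-corrected input).
#' @param X_new Numeric matrix with p columns, raw (uncentered) scale.
#' @param centering A `spectra_dataset` carrying the training centering
#'   constants.
#' @return Numeric vector of predictions on the original response scale.
#' @export
predict_response <- function(beta, X_new, centering) {
  stopifnot(inherits(centering, "spectra_dataset"))
  X_new <- as_numeric_matrix(X_new)
  if (ncol(X_new) != length(beta)) {
    stop("`X_new` has ", ncol(X_new), " columns but `beta` has length ",
         length(beta), call. = FALSE)
  }
  Xc <- sweep(X_new, 2, centering$x_center, "-")
  if (any(centering$x_scale != 1)) Xc <- sweep(Xc, 2, centering$x_scale, "/")
  drop(Xc %*% beta) + centering$y_center
}

#' Variance decomposition of an OSC + PLS fit
#'
#' Tabulates where the sums of squares go: for each OSC component the
#' fraction of the total X sum of squares it removes; for each PLS component
#' the fraction of the corrected-matrix (`X_osc`) sum of squares and of the Y
#' sum of squares it captures. A `residual` row closes each part to 1.
#' The `X_osc` part also reports (in the `osc` component rows) the fraction
#' of total X remaining after correction.
#'
#' @param osc An `osc_model`.
#' @param pls An `opls_model` fitted on `osc$X_osc`.
#' @return A tidy tibble with columns `part` (one of `"X_orth"`, `"X_osc"`,
#'   `"Y"`), `component` (e.g. `"OSC1"`, `"PLS1"`, `"residual"`) and
#'   `fraction`.
#' @export
variance_table <- function(osc, pls) {
  stopifnot(inherits(osc, "osc_model"), inherits(pls, "opls_model"))
  k <- osc$n_components
  A <- pls$A
  # X_osc and X_orth are Frobenius-orthogonal, so their sums of squares add
  ss_x_total <- sum(osc$X_osc^2) + sum(osc$X_orth^2)
  # per-component removed fraction: ||t_j p_j'||^2 = ||t_j||^2 (unit loadings)
  osc_fracs <- if (k > 0L) colSums(osc$t_osc^2) / ss_x_total else numeric(0)
  rows <- list()
  if (k > 0L) {
    rows$x_orth <- tibble::tibble(
      part = "X_orth", component = paste0("OSC", seq_len(k)), fraction = osc_fracs
    )
  }
  # X_osc: fraction of total X left after correction, then per-PLS-component
  # fractions of the X_osc sum of squares, then the unexplained residual.
  resid_x <- 1 - sum(pls$var_x_per_comp)
  rows$x_osc <- tibble::tibble(
    part = "X_osc",
    component = c(if (k > 0L) "OSC" else character(0),
                  paste0("PLS", seq_len(A)), "residual"),
    fraction = c(if (k > 0L) osc$frac_var_osc else numeric(0),
                 pls$var_x_per_comp, resid_x)
  )
  rows$y <- tibble::tibble(
    part = "Y",
    component = c(paste0("PLS", seq_len(A)), "residual"),
    fraction = c(pls$var_y_per_comp, 1 - sum(pls$var_y_per_comp))
  )
  dplyr::bind_rows(rows)
}
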