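#' Project a response onto the column space of X
#'
#' Computes \eqn{\hat Y = P_X Y}, the orthogonal projection of `Y` onto the
#' column space of `X`, through a rank-revealing singular value decomposition
#' (singular values below `max(n, p) * eps * sigma_max` are treated as zero).
#' For underdetermined systems (`p > n` with full row rank), common in
#' spectral data, the column space is all of R^n and the projection returns
#' `Y` unchanged.
#'
#' @param X Centered numeric matrix (n x p).
#' @param Y Centered numeric response of length n.
#' @return Numeric vector of length n.
#' @export
project_onto_columns <- function(X, Y) {
  X <- as_numeric_matrix(X)
  Y <- as.numeric(Y)
  if (nrow(X) != length(Y)) {
    stop("`X` has ", nrow(X), " rows but `Y` has length ", length(Y), call. = FALSE)
  }
  sv <- svd(X, nu = min(dim(X)), nv = 0)
  r <- svd_rank(sv$d, dim(X))
  if (r == 0L) return(rep(0, length(Y)))
  U <- sv$u[, seq_len(r), drop = FALSE]
  drop(U %*% crossprod(U, Y))
}

svd_rank <- function(d, dims) {
  if (length(d) == 0L || d[1] <= 0) return(0L)
  sum(d > max(dims) * .Machine$double.eps * d[1])
}

#' Fit a direct orthogonal signal correction model
#'
#' Decomposes a centered predictor matrix `X` into a part orthogonal to the
#' response (`X_orth`, the removed systematic variation) and a corrected part
#' (`X_osc`) that preserves the X-Y covariance. The procedure is direct (no
#' iteration): project `Y` onto the column space of `X` to get
#' \eqn{\hat Y}; form the anti-projection \eqn{A_{\hat Y} X} of `X` away from
#' \eqn{\hat Y}; take its leading principal component(s) as the orthogonal
#' scores `t_osc` and loadings `p_osc`; express the scores in terms of the
#' original variables via the Moore-Penrose pseudoinverse,
#' \eqn{r_{osc} = X^\dagger t_{osc}}; and set
#' \deqn{X^{ORTH} = t_{osc} p_{osc}^\top, \qquad
#'       X^{OSC} = X - X r_{osc} p_{osc}^\top.}
#'
#' By construction every orthogonal score is exactly orthogonal to `Y`, so
#' \eqn{(X^{OSC})^\top Y = X^\top Y}: the correction removes response-
#' orthogonal variation only. One component is usually sufficient (it
#' typically absorbs baseline-like variation); the weight/loading pair is kept
#' so the same correction can be applied to new samples.
#'
#' @param data A `spectra_dataset` from [mean_center()], or a centered
#'   numeric matrix (then `Y` must be supplied).
#' @param n_components Number of orthogonal components to remove (default 1).
#' @param Y Centered response, only when `data` is a bare matrix.
#' @return An object of class `osc_model`: list with `t_osc` (n x k),
#'   `p_osc` (p x k), `r_osc` (p x k), `X_osc`, `X_orth`, `frac_var_orth`,
#'   `frac_var_osc`, `n_components`.
#' @export
fit_osc <- function(data, n_components = 1L, Y = NULL) {
  if (inherits(data, "spectra_dataset")) {
    X <- data$X
    Y <- data$Y
  } else {
    X <- as_numeric_matrix(data)
    if (is.null(Y)) stop("supply `Y` when `data` is a bare matrix", call. = FALSE)
    Y <- as.numeric(Y)
  }
  n <- nrow(X)
  p <- ncol(X)
  k <- as.integer(n_components)
  if (k < 1L || k > min(n, p) - 1L) {
    stop("`n_components` must be between 1 and min(n, p) - 1", call. = FALSE)
  }
  ss_x <- sum(X^2)
  if (ss_x <= 0) stop("`X` has zero variance; nothing to correct", call. = FALSE)

  sv_x <- svd(X)
  rank_x <- svd_rank(sv_x$d, dim(X))
  Ur <- sv_x$u[, seq_len(rank_x), drop = FALSE]
  y_hat <- drop(Ur %*% crossprod(Ur, Y))

  # anti-projection of X away from the fitted response direction
  ss_yhat <- sum(y_hat^2)
  if (ss_yhat > max(n, p) * .Machine$double.eps * ss_x) {
    Z <- X - tcrossprod(y_hat / ss_yhat, crossprod(X, y_hat))
  } else {
    Z <- X
  }

  sz <- svd(Z, nu = k, nv = k)
  tol_z <- max(dim(Z)) * .Machine$double.eps * max(sz$d[1], 0)
  rank_z <- sum(sz$d > tol_z)
  if (rank_z == 0L) {
    # no response-orthogonal structure: correction is the identity
    return(structure(
      list(
        t_osc = matrix(0, n, 0), p_osc = matrix(0, p, 0),
        r_osc = matrix(0, p, 0), X_osc = X, X_orth = matrix(0, n, p),
        frac_var_orth = 0, frac_var_osc = 1, n_components = 0L
      ),
      class = "osc_model"
    ))
  }
  if (k > rank_z) {
    stop("`n_components` (", k, ") exceeds the rank (", rank_z,
         ") of the response-orthogonal part of `X`", call. = FALSE)
  }

  t_osc <- sz$u %*% diag(sz$d[seq_len(k)], k, k)
  p_osc <- sz$v
  # deterministic sign: largest-magnitude loading entry positive
  for (j in seq_len(k)) {
    i_max <- which.max(abs(p_osc[, j]))
    if (p_osc[i_max, j] < 0) {
      p_osc[, j] <- -p_osc[, j]
      t_osc[, j] <- -t_osc[, j]
    }
  }

  # r_osc = pseudoinverse(X) %*% t_osc, via the SVD of X already at hand
  dr <- sv_x$d[seq_len(rank_x)]
  r_osc <- sv_x$v[, seq_len(rank_x), drop = FALSE] %*%
    (crossprod(Ur, t_osc) / dr)

  X_orth <- tcrossprod(t_osc, p_osc)
  X_osc <- X - X %*% r_osc %*% t(p_osc)

  structure(
    list(
      t_osc = t_osc, p_osc = p_osc, r_osc = r_osc,
      X_osc = X_osc, X_orth = X_orth,
      frac_var_orth = sum(X_orth^2) / ss_x,
      frac_var_osc = sum(X_osc^2) / ss_x,
      n_components = k
    ),
    class = "osc_model"
  )
}

#' @export
print.osc_model <- function(x, ...) {
  cat("<osc_model> ", x$n_components, " orthogonal component(s); ",
      sprintf("%.1f%%", 100 * x$frac_var_orth),
      " of X sum of squares removed\n", sep = "")
  invisible(x)
}

#' Apply a fitted orthogonal signal correction to new samples
#'
#' Removes the training-set orthogonal directions from a new matrix using the
#' frozen weights and loadings: `X_new - X_new r_osc p_osc'`. `X_new` must be
#' centered with the training column means.
#'
#' @param model An `osc_model` from [fit_osc()].
#' @param X_new Centered numeric matrix with the same number of columns as
#'   the training data.
#' @return The corrected matrix, same shape as `X_new`.
#' @export
apply_osc <- function(model, X_new) {
  stopifnot(inherits(model, "osc_model"))
  X_new <- as_numeric_matrix(X_new)
  if (ncol(X_new) != nrow(model$r_osc) && model$n_components > 0L) {
    stop("`X_new` has ", ncol(X_new), " columns; model expects ",
         nrow(model$r_osc), call. = FALSE)
  }
  if (model$n_components == 0L) return(X_new)
  X_new - X_new %*% model$r_osc %*% t(model$p_osc)
}
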