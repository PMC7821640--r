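#' Predictive Q-squared
#'
#' The fraction of (uncentered) response variation described by held-out
#' predictions: \eqn{Q^2 = 1 - \sum_i (y_i - \hat y_i)^2 / \sum_i y_i^2}.
#' Note the denominator is the raw sum of squares of the observed test
#' responses, not the centered one; `q_squared` is therefore 1 for perfect
#' prediction and 0 for the all-zero prediction.
#'
#' @param y_test Observed responses.
#' @param y_hat Predicted responses (same length).
#' @return A single number (can be negative for predictions worse than zero).
#' @export
q_squared <- function(y_test, y_hat) {
  if (length(y_test) != length(y_hat)) stop("length mismatch", call. = FALSE)
  ss <- sum(y_test^2)
  if (ss == 0) stop("Q^2 undefined: sum of squared responses is zero", call. = FALSE)
  1 - sum((y_test - y_hat)^2) / ss
}

#' Precision of a variable selection
#'
#' The fraction of selected variables that are truly relevant:
#' `|selected intersect truth| / |selected|`. Undefined (returned as `NA`)
#' for an empty selection.
#'
#' @param selected Integer indices of selected variables.
#' @param truth Integer indices of the ground-truth relevant variables.
#' @return A number in \[0, 1\], or `NA_real_` when nothing was selected.
#' @export
precision_metric <- function(selected, truth) {
  if (length(selected) == 0L) return(NA_real_)
  length(intersect(selected, truth)) / length(selected)
}

#' Train/test evaluation of a variable selector
#'
#' Repeats a random 70/30 split protocol: run the selector on the training
#' part, refit an ordinary least-squares model of Y on the selected columns
#' (minimum-norm solution when rank-deficient), predict the held-out part,
#' and accumulate the mean squared error, [q_squared()], the precision
#' against `truth` (when given) and the selected-variable count. When a
#' repeat selects nothing, its MSE and Q-squared come from the intercept-only
#' (training-mean) model and its precision is missing.
#'
#' @param X Predictor matrix (samples in rows), raw scale.
#' @param Y Response vector.
#' @param selector A function `(X_train, Y_train) -> integer indices`, e.g.
#'   a wrapper around [oplsr()], [fdr_select()] or [lasso_select()].
#' @param split_fraction Training fraction (default 0.7).
#' @param repeats Number of random splits (default 100).
#' @param truth Optional ground-truth indices for precision.
#' @param seed Optional integer seed.
#' @return A list with `summary` (one-row tibble of means: `mse`, `q2`,
#'   `precision`, `n_selected`) and `repeats` (per-split tibble).
#' @export
train_test_evaluate <- function(X, Y, selector, split_fraction = 0.7,
                                repeats = 100L, truth = NULL, seed = NULL) {
  X <- as_numeric_matrix(X)
  Y <- as.numeric(Y)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(X)
  n_train <- round(split_fraction * n)
  if (n_train < 3L || n_train >= n) stop("degenerate train/test split", call. = FALSE)

  one <- function(rep_id) {
    idx <- sample.int(n, n_train)
    Xtr <- X[idx, , drop = FALSE]
    ytr <- Y[idx]
    Xte <- X[-idx, , drop = FALSE]
    yte <- Y[-idx]
    sel <- sort(as.integer(selector(Xtr, ytr)))
    if (length(sel) == 0L) {
      yhat <- rep(mean(ytr), length(yte))
    } else {
      b <- minimum_norm_ls(scale(Xtr[, sel, drop = FALSE], scale = FALSE),
                           ytr - mean(ytr))
      yhat <- drop(sweep(Xte[, sel, drop = FALSE], 2,
                         colMeans(Xtr[, sel, drop = FALSE]), "-") %*% b) + mean(ytr)
    }
    tibble::tibble(
      repeat_id = rep_id,
      mse = mean((yte - yhat)^2),
      q2 = q_squared(yte, yhat),
      precision = if (is.null(truth)) NA_real_ else precision_metric(sel, truth),
      n_selected = length(sel)
    )
  }
  per <- purrr::map_dfr(seq_len(repeats), one)
  list(
    summary = tibble::tibble(
      mse = mean(per$mse),
      q2 = mean(per$q2),
      precision = mean(per$precision, na.rm = TRUE),
      n_selected = mean(per$n_selected)
    ),
    repeats = per
  )
}

# minimum-norm least squares via rank-truncated SVD
minimum_norm_ls <- function(X, y) {
  sv <- svd(X)
  r <- svd_rank(sv$d, dim(X))
  if (r == 0L) return(rep(0, ncol(X)))
  drop(sv$v[, seq_len(r), drop = FALSE] %*%
         (crossprod(sv$u[, seq_len(r), drop = FALSE], y) / sv$d[seq_len(r)]))
}
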