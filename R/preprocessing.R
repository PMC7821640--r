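#' Mean-center a predictor matrix and response
#'
#' Centers every column of `X` and the response `Y` to mean zero, keeping the
#' centering constants so that new samples (and predictions) can be put on the
#' training scale. Optionally scales columns to unit standard deviation.
#'
#' All downstream modelling in this package (orthogonal signal correction,
#' PLS, permutation testing) assumes centered inputs; `mean_center()` is the
#' canonical way to produce them.
#'
#' @param X A numeric matrix or data frame, samples in rows, features in
#'   columns. Column names, when present, are kept as feature identifiers.
#' @param Y A numeric response vector of length `nrow(X)`; binary class
#'   labels coded 0/1 are allowed.
#' @param scale Logical; also divide each column by its standard deviation
#'   (columns with zero variance are left unscaled). Default `FALSE`:
#'   spectral intensities are usually analysed on their native scale.
#' @return An object of class `spectra_dataset`: a list with centered `X`,
#'   centered `Y`, `x_center`, `x_scale`, `y_center`, `feature_ids`, `n`, `p`.
#' @examples
#' d <- mean_center(matrix(c(1, 3, 3, 5), 2), c(0, 2))
#' colMeans(d$X)  # all zero
#' @export
mean_center <- function(X, Y, scale = FALSE) {
  X <- as_numeric_matrix(X, "X")
  Y <- as.numeric(Y)
  if (nrow(X) != length(Y)) {
    stop("`X` has ", nrow(X), " rows but `Y` has length ", length(Y), call. = FALSE)
  }
  if (anyNA(X) || any(!is.finite(X))) {
    stop("`X` contains missing or non-finite values", call. = FALSE)
  }
  if (anyNA(Y) || any(!is.finite(Y))) {
    stop("`Y` contains missing or non-finite values", call. = FALSE)
  }
  ids <- colnames(X)
  if (is.null(ids)) ids <- as.character(seq_len(ncol(X)))
  x_center <- colMeans(X)
  Xc <- sweep(X, 2, x_center, "-")
  x_scale <- rep(1, ncol(X))
  if (isTRUE(scale)) {
    s <- apply(Xc, 2, stats::sd)
    x_scale <- ifelse(s > 0, s, 1)
    Xc <- sweep(Xc, 2, x_scale, "/")
  }
  y_center <- mean(Y)
  structure(
    list(
      X = Xc, Y = Y - y_center,
      x_center = x_center, x_scale = x_scale, y_center = y_center,
      feature_ids = ids, n = nrow(Xc), p = ncol(Xc)
    ),
    class = "spectra_dataset"
  )
}

#' @export
print.spectra_dataset <- function(x, ...) {
  cat("<spectra_dataset> ", x$n, " samples x ", x$p, " features (centered)\n", sep = "")
  invisible(x)
}

# Coerce a data frame / matrix to a plain numeric matrix with checks.
as_numeric_matrix <- function(X, what = "X") {
  if (is.data.frame(X)) X <- as.matrix(X)
  if (!is.matrix(X)) X <- matrix(X, ncol = 1L)
  if (!is.numeric(X)) stop("`", what, "` must be numeric", call. = FALSE)
  X
}

#' Per-feature correlation p-values against the response
#'
#' For each column of a centered dataset, tests the Pearson correlation with
#' `Y` against zero via the two-sided t-test with `n - 2` degrees of freedom.
#' For a 0/1-coded response this is equivalent to the pooled two-sample
#' t-test. Constant (zero-variance) columns have an undefined correlation and
#' are assigned p = 1, so dead spectral channels are never admitted.
#'
#' This is the pre-filter that restricts which variables enter the
#' permutation test: only features with p below `alpha_f` ("filtered-in")
#' are carried forward, which removes noise variables from the whole
#' procedure and controls its cost.
#'
#' @param data A `spectra_dataset` from [mean_center()].
#' @param alpha_f Filtering level in (0, 1]; features with correlation
#'   p-value strictly below `alpha_f` are kept. Default 0.05.
#' @return A tibble with one row per feature: `index`, `feature_id`,
#'   `correlation`, `p_value`, `kept`; the filtering level is stored in the
#'   `alpha_f` attribute.
#' @export
correlation_filter <- function(data, alpha_f = 0.05) {
  stopifnot(inherits(data, "spectra_dataset"))
  if (!is.numeric(alpha_f) || length(alpha_f) != 1L || alpha_f <= 0 || alpha_f > 1) {
    stop("`alpha_f` must be a single value in (0, 1]", call. = FALSE)
  }
  n <- data$n
  if (n < 3L) stop("need at least 3 samples to test correlations", call. = FALSE)
  p <- feature_pvalues(data$X, data$Y)
  res <- tibble::tibble(
    index = seq_len(data$p),
    feature_id = data$feature_ids,
    correlation = p$r,
    p_value = p$p,
    kept = p$p < alpha_f
  )
  attr(res, "alpha_f") <- alpha_f
  res
}

# Pearson correlation of each centered column with centered y, plus the
# two-sided t-test p-value (df = n - 2). Zero-variance columns get r = 0,
# p = 1. Vectorised over columns.
feature_pvalues <- function(X, y) {
  n <- nrow(X)
  sy <- sqrt(sum(y^2))
  sx <- sqrt(colSums(X^2))
  r <- rep(0, ncol(X))
  ok <- sx > 0 & sy > 0
  if (any(ok)) r[ok] <- drop(crossprod(X[, ok, drop = FALSE], y)) / (sx[ok] * sy)
  # guard rounding: |r| can exceed 1 by eps for exact linear dependence
  r <- pmin(1, pmax(-1, r))
  p <- rep(1, ncol(X))
  tt <- abs(r[ok]) * sqrt((n - 2) / pmax(1 - r[ok]^2, .Machine$double.eps))
  p[ok] <- 2 * stats::pt(tt, df = n - 2, lower.tail = FALSE)
  list(r = r, p = p)
}
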