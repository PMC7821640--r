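#' Select variables by false discovery rate on individual correlations
#'
#' Baseline selector operating on each variable's individual association
#' with the response: the same correlation t-test used by
#' [correlation_filter()], followed by the Benjamini-Hochberg step-up
#' procedure at level `q`. Variables whose BH-adjusted p-value is at most
#' `q` are selected.
#'
#' @param data A `spectra_dataset` from [mean_center()].
#' @param q FDR level in (0, 1).
#' @return Sorted integer vector of selected indices.
#' @export
fdr_select <- function(data, q = 0.05) {
  stopifnot(inherits(data, "spectra_dataset"))
  if (q <= 0 || q >= 1) stop("`q` must be in (0, 1)", call. = FALSE)
  p <- feature_pvalues(data$X, data$Y)$p
  which(stats::p.adjust(p, method = "BH") <= q)
}

#' Select variables by the lasso at a fixed penalty
#'
#' Baseline selector: L1-penalised least squares (elastic net with alpha = 1,
#' fitted by coordinate descent via \pkg{glmnet}) at a single fixed penalty
#' `lambda`; variables with a nonzero coefficient are selected. Columns are
#' standardised by default, the intercept is unpenalised, and the penalty is
#' on the usual `(1/2n) ||y - Xb||^2 + lambda ||b||_1` scale.
#'
#' @param data A `spectra_dataset` from [mean_center()].
#' @param lambda Penalty value (> 0).
#' @param standardize Standardise columns inside the fit (default `TRUE`).
#' @return Sorted integer vector of selected indices.
#' @export
lasso_select <- function(data, lambda, standardize = TRUE) {
  stopifnot(inherits(data, "spectra_dataset"))
  if (!is.numeric(lambda) || lambda <= 0) stop("`lambda` must be positive", call. = FALSE)
  if (ncol(data$X) == 1L) {
    # univariate case in closed form (soft-thresholding); the objective is
    # (1/2n)||y - xb||^2 + lambda|b|, matching the multivariate fit below
    n <- nrow(data$X)
    x <- data$X[, 1]
    if (standardize) {
      s <- sqrt(sum(x^2) / n)
      if (s > 0) x <- x / s
    }
    z <- sum(x * data$Y) / n
    return(if (stats::sd(x) > 0 && abs(z) > lambda) 1L else integer(0))
  }
  fit <- glmnet::glmnet(data$X, data$Y, alpha = 1, standardize = standardize,
                        intercept = TRUE, thresh = 1e-10)
  b <- glmnet::coef.glmnet(fit, s = lambda, exact = TRUE,
                           x = data$X, y = data$Y, alpha = 1,
                           standardize = standardize, intercept = TRUE,
                           thresh = 1e-10)
  which(as.numeric(b)[-1] != 0)
}
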