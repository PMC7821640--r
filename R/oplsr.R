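#' Orthogonal-PLS regression feature selection
#'
#' End-to-end selection of response-associated variables in a sample-by-
#' feature matrix. The pipeline: mean-center X and Y; pre-filter features by
#' the significance of their individual correlation with Y at level
#' `alpha_f`; on the filtered-in columns, remove the response-orthogonal
#' variation by direct orthogonal signal correction; fit a PLS regression
#' with orthonormal scores on the corrected matrix; form the regression
#' vector (`beta_b` against the original X by default); build empirical null
#' distributions of each candidate coefficient by within-column permutation
#' refits; and select the variables whose observed coefficient is
#' significant at level `alpha_pm` against its null.
#'
#' @param data A data frame or numeric matrix of predictors (samples in
#'   rows), optionally containing the response as a column.
#' @param response The response: a numeric vector of length `nrow(data)`, or
#'   the (quoted or bare) name of a column of `data`. 0/1 class labels are
#'   allowed.
#' @param alpha_f Correlation pre-filter level (default 0.05).
#' @param A Number of predictive PLS components (default 1).
#' @param n_osc Number of orthogonal components removed (default 1;
#'   one component is typically sufficient and keeps the correction
#'   interpretable).
#' @param cfg A [permutation_config()].
#' @param scale Scale columns to unit variance before modelling (default
#'   `FALSE`).
#' @param restrict Fit OSC/PLS on the filtered-in columns only (default
#'   `TRUE`), so noise variables passed over by the pre-filter cannot leak
#'   into the latent components; set `FALSE` to model the full matrix.
#' @param keep_null Keep the per-variable null samples in the returned
#'   object (needed for null-distribution plots; default `FALSE`).
#' @param seed Optional integer seed for the permutation randomness.
#' @return An object of class `oplsr`, with components `results` (tibble:
#'   `index`, `feature_id`, `beta`, `p_value`, `ci_low`, `ci_high`,
#'   `filtered_in`, `selected`), `osc`, `pls`, `centering`, `filter`,
#'   `config`, and counts. Use [generics::tidy()], [generics::glance()],
#'   [ggplot2::autoplot()] on it.
#' @examples
#' sim <- simulate_layers(n = 40, seed = 1)
#' fit <- oplsr(sim$X, sim$Y, cfg = permutation_config(B = 99), seed = 1)
#' dplyr::filter(generics::tidy(fit), selected)
#' @export
oplsr <- function(data, response, alpha_f = 0.05, A = 1L, n_osc = 1L,
                  cfg = permutation_config(), scale = FALSE,
                  restrict = TRUE, keep_null = FALSE, seed = NULL) {
  xy <- split_response(data, rlang::enquo(response))
  if (!is.null(seed)) set.seed(seed)

  ds <- mean_center(xy$X, xy$Y, scale = scale)
  filt <- correlation_filter(ds, alpha_f = alpha_f)
  kept <- which(filt$kept)
  if (length(kept) == 0L) {
    stop("no variables pass the correlation pre-filter at alpha_f = ",
         alpha_f, call. = FALSE)
  }

  model_cols <- if (restrict) kept else seq_len(ds$p)
  Xm <- ds$X[, model_cols, drop = FALSE]
  osc <- fit_osc(Xm, n_components = n_osc, Y = ds$Y)
  pls <- fit_opls(osc$X_osc, ds$Y, A = A)
  coefs <- opls_coefficients(osc, pls)
  beta_model <- if (cfg$beta_kind == "b") coefs$beta_b else coefs$beta_a

  # permutation nulls for the filtered-in columns (positions within Xm)
  cand_pos <- match(kept, model_cols)
  nul <- permutation_null(osc$X_osc, ds$Y, osc, cfg = cfg, A = A)
  null_kept <- nul$samples[cand_pos]
  pv_kept <- permutation_pvalues(beta_model[cand_pos], null_kept, B = cfg$B)
  ci_kept <- permutation_intervals(null_kept, alpha_pm = cfg$alpha_pm)

  alpha_eff <- if (cfg$bonferroni) cfg$alpha_pm / length(kept) else cfg$alpha_pm

  # filtered-out variables are reported with coefficient 0 (when restricted)
  # and p = 1; intervals exist only for permutation-tested variables
  beta_report <- rep(0, ds$p)
  beta_report[model_cols] <- beta_model
  p_full <- rep(1, ds$p)
  p_full[kept] <- pv_kept
  ci_lo <- ci_hi <- rep(NA_real_, ds$p)
  ci_lo[kept] <- ci_kept$ci_low
  ci_hi[kept] <- ci_kept$ci_high
  selected <- p_full < alpha_eff & seq_len(ds$p) %in% kept

  results <- tibble::tibble(
    index = seq_len(ds$p),
    feature_id = ds$feature_ids,
    beta = beta_report,
    p_value = p_full,
    ci_low = ci_lo,
    ci_high = ci_hi,
    filtered_in = filt$kept,
    selected = selected
  )

  structure(
    list(
      results = results,
      osc = osc, pls = pls, centering = ds, filter = filt,
      config = c(cfg, list(alpha_f = alpha_f, A = A, n_osc = n_osc,
                           scale = scale, restrict = restrict, seed = seed,
                           alpha_effective = alpha_eff)),
      n_iterations = nul$n_iterations,
      null_samples = if (keep_null) stats::setNames(null_kept, ds$feature_ids[kept]) else NULL,
      selected = which(selected),
      filtered_in = kept
    ),
    class = "oplsr"
  )
}

# Resolve the response argument: a column of `data` (by name) or a vector.
split_response <- function(data, response_quo) {
  resp <- rlang::eval_tidy(response_quo, data = as.data.frame(data))
  if (is.character(resp) && length(resp) == 1L && !is.null(colnames(data)) &&
      resp %in% colnames(data)) {
    y <- data[[resp]]
    X <- data[, setdiff(colnames(data), resp), drop = FALSE]
  } else if (length(resp) == nrow(as.matrix(data))) {
    y <- as.numeric(resp)
    X <- data
    nm <- tryCatch(rlang::as_name(response_quo), error = function(e) NULL)
    if (!is.null(nm) && !is.null(colnames(X)) && nm %in% colnames(X)) {
      X <- X[, setdiff(colnames(X), nm), drop = FALSE]
    }
  } else {
    stop("`response` must be a response vector or the name of a column of `data`",
         call. = FALSE)
  }
  list(X = as_numeric_matrix(X), Y = y)
}

#' @export
print.oplsr <- function(x, ...) {
  cat("Orthogonal-PLS regression selection\n")
  cat("  features:    ", nrow(x$results), "\n", sep = "")
  cat("  filtered-in: ", length(x$filtered_in),
      " (alpha_f = ", x$config$alpha_f, ")\n", sep = "")
  cat("  selected:    ", length(x$selected),
      " (alpha_pm = ", x$config$alpha_pm,
      if (x$config$bonferroni) ", Bonferroni" else "", ", beta_",
      x$config$beta_kind, ")\n", sep = "")
  cat("  OSC components removed ", sprintf("%.1f%%", 100 * x$osc$frac_var_orth),
      " of X sum of squares\n", sep = "")
  invisible(x)
}

#' Tidy the per-feature results of an `oplsr` fit
#'
#' @param x An `oplsr` object.
#' @param ... Unused.
#' @return The per-feature results tibble (`index`, `feature_id`, `beta`,
#'   `p_value`, `ci_low`, `ci_high`, `filtered_in`, `selected`).
#' @export
tidy.oplsr <- function(x, ...) x$results

#' One-row summary of an `oplsr` fit
#'
#' @param x An `oplsr` object.
#' @param ... Unused.
#' @return A one-row tibble: feature counts, filtering/selection levels, and
#'   the variance fractions removed and captured.
#' @export
glance.oplsr <- function(x, ...) {
  tibble::tibble(
    n = x$centering$n,
    p = x$centering$p,
    n_filtered_in = length(x$filtered_in),
    n_selected = length(x$selected),
    alpha_f = x$config$alpha_f,
    alpha_pm = x$config$alpha_pm,
    beta_kind = x$config$beta_kind,
    A = x$config$A,
    frac_var_orth = x$osc$frac_var_orth,
    frac_y_pls1 = x$pls$var_y_per_comp[1]
  )
}

#' Plot an OPLS regression vector with permutation intervals
#'
#' Observed coefficients as points, permutation-null confidence intervals as
#' vertical segments for the filtered-in variables, and selected variables
#' highlighted.
#'
#' @param object An `oplsr` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.oplsr <- function(object, ...) {
  res <- object$results
  ggplot2::ggplot(res, ggplot2::aes(x = .data$index, y = .data$beta)) +
    ggplot2::geom_segment(
      data = dplyr::filter(res, .data$filtered_in),
      ggplot2::aes(xend = .data$index, y = .data$ci_low, yend = .data$ci_high),
      colour = "grey60", linewidth = 0.3
    ) +
    ggplot2::geom_point(size = 0.6, colour = "steelblue") +
    ggplot2::geom_point(
      data = dplyr::filter(res, .data$selected),
      shape = 1, size = 2, colour = "black"
    ) +
    ggplot2::labs(
      x = "variable index", y = "regression coefficient",
      title = "OPLS regression vector",
      subtitle = "segments: permutation null intervals; circles: selected variables"
    ) +
    ggplot2::theme_minimal()
}
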