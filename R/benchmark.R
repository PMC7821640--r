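#' Benchmark selectors on replicated three-layer simulations
#'
#' Runs the full comparison protocol on the layered generator: for each of
#' `R` replicate datasets (each with its own seed drawn from the master
#' seed), runs every requested method at every level, tallies how many
#' selected variables fall in each layer, and averages the counts over
#' replicates. The variance decomposition of the OSC + PLS fit is averaged
#' over replicates as well.
#'
#' Methods: `"oplsr_a"` and `"oplsr_b"` (permutation selection on the
#' `beta_a` / `beta_b` regression vector; `level` is the pre-filter
#' `alpha_f`), `"fdr"` (BH step-up; `level` is the q-value), `"lasso"`
#' (`level` is the penalty `lambda`).
#'
#' @param R Number of replicate datasets (at least 10 for meaningful means;
#'   default 100).
#' @param methods Character vector of methods to run.
#' @param levels Numeric vector of significance/penalty levels.
#' @param A Predictive PLS components for the OPLSR methods.
#' @param cfg [permutation_config()] for the OPLSR methods (its `beta_kind`
#'   is overridden per method).
#' @param n Samples per replicate dataset (default 40).
#' @param seed Master seed.
#' @return A list of class `oplsr_benchmark`: `counts` (tibble: `method`,
#'   `level`, `layer`, `mean_count`, `se_count`), `variance` (tibble of mean
#'   variance-table fractions over replicates), `R`, `seed`.
#' @export
run_benchmark <- function(R = 100L, methods = c("oplsr_b", "fdr"),
                          levels = 0.05, A = 1L, cfg = permutation_config(),
                          n = 40L, seed = 1L) {
  R <- as.integer(R)
  if (R < 2L) stop("`R` must be at least 2", call. = FALSE)
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, R)
  var_method <- intersect(methods, c("oplsr_b", "oplsr_a"))[1]

  count_rows <- list()
  var_rows <- list()
  for (i in seq_len(R)) {
    sim <- simulate_layers(n = n, seed = rep_seeds[i])
    ds <- mean_center(sim$X, sim$Y)
    for (m in methods) {
      for (lev in levels) {
        sel <- switch(
          m,
          fdr = fdr_select(ds, q = lev),
          lasso = lasso_select(ds, lambda = lev),
          oplsr_a = ,
          oplsr_b = {
            kind <- if (m == "oplsr_a") "a" else "b"
            cfg_m <- permutation_config(
              B = cfg$B, subset_fraction = cfg$subset_fraction,
              alpha_pm = cfg$alpha_pm, bonferroni = cfg$bonferroni,
              beta_kind = kind
            )
            # offset the permutation seed from the generation seed so the
            # two RNG streams are distinct
            fit <- oplsr(sim$X, sim$Y, alpha_f = lev, A = A, cfg = cfg_m,
                         seed = (rep_seeds[i] + 104729L) %% (.Machine$integer.max - 1L))
            if (!is.na(var_method) && m == var_method && lev == levels[1]) {
              vt <- variance_table(fit$osc, fit$pls)
              vt$replicate <- i
              var_rows[[length(var_rows) + 1L]] <- vt
            }
            fit$selected
          },
          stop("unknown method: ", m, call. = FALSE)
        )
        lc <- layer_counts(sel, sim$layout)
        lc$method <- m
        lc$level <- lev
        lc$replicate <- i
        count_rows[[length(count_rows) + 1L]] <- lc
      }
    }
  }
  counts <- dplyr::bind_rows(count_rows) |>
    dplyr::group_by(.data$method, .data$level, .data$layer) |>
    dplyr::summarise(
      mean_count = mean(.data$count),
      se_count = stats::sd(.data$count) / sqrt(dplyr::n()),
      .groups = "drop"
    )
  variance <- if (length(var_rows) > 0) {
    dplyr::bind_rows(var_rows) |>
      dplyr::group_by(.data$part, .data$component) |>
      dplyr::summarise(mean_fraction = mean(.data$fraction), .groups = "drop")
  } else {
    tibble::tibble(part = character(0), component = character(0),
                   mean_fraction = numeric(0))
  }
  structure(
    list(counts = counts, variance = variance, R = R, seed = seed,
         methods = methods, levels = levels),
    class = "oplsr_benchmark"
  )
}

#' @export
print.oplsr_benchmark <- function(x, ...) {
  cat("<oplsr_benchmark> ", x$R, " replicates; methods: ",
      paste(x$methods, collapse = ", "), "; levels: ",
      paste(x$levels, collapse = ", "), "\n", sep = "")
  print(tidyr::pivot_wider(x$counts[, c("method", "level", "layer", "mean_count")],
                           names_from = "layer", values_from = "mean_count"))
  invisible(x)
}

#' Mean selected-variable counts per layer as a wide table
#'
#' @param x An `oplsr_benchmark`.
#' @param ... Unused.
#' @return A tibble with one row per method and level and one column per
#'   layer.
#' @export
tidy.oplsr_benchmark <- function(x, ...) {
  tidyr::pivot_wider(x$counts[, c("method", "level", "layer", "mean_count")],
                     names_from = "layer", values_from = "mean_count")
}

#' Plot mean layer counts of a benchmark run
#'
#' @param object An `oplsr_benchmark`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.oplsr_benchmark <- function(object, ...) {
  ggplot2::ggplot(
    object$counts,
    ggplot2::aes(x = .data$layer, y = .data$mean_count, fill = .data$method)
  ) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~level, labeller = ggplot2::label_both) +
    ggplot2::labs(x = NULL, y = "mean selected variables") +
    ggplot2::theme_minimal()
}
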