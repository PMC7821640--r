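#' Simulate a three-layer collinear benchmark dataset
#'
#' Generates a sample-by-feature matrix with a known layered dependence
#' structure and a binary response, emulating the multi-level collinearity of
#' spectral and metabolomic data. The default dimensions are 40 samples by
#' 1000 variables:
#'
#' * **Layer 1** (30 variables): nine individually strong variables --
#'   `x1..x4 ~ U(0,1) + 0.8 - 2Y` (high at label 0) and
#'   `x5..x9 ~ U(0,1) - 1.2 + 2Y` (high at label 1) -- plus seven
#'   group-wise trivariate-normal triples `x10..x30` with mean `Y * (1,2,3)`
#'   and covariance `[[12,10,8],[10,12,10],[8,10,12]]`, which separate the
#'   labels jointly rather than individually.
#' * **Layer 2** (90 variables, `x31..x120`): each layer-1 variable `x_q` is
#'   decomposed into three children `w_i * (x_q + eps)`, with weights
#'   `w_i = u_i / (u1+u2+u3)`, `u_i ~ U(0,1)` drawn once per parent, and a
#'   per-sample noise `eps ~ N(0, sd = |x_q|/10)`; the three children sum to
#'   `x_q + eps` exactly.
#' * **Layer 3** (270 variables, `x121..x390`): the same decomposition
#'   applied to every layer-2 variable.
#' * **Noise** (610 variables, `x391..x1000`): i.i.d. standard normal.
#'
#' The response is i.i.d. Bernoulli(0.4), so 16 of 40 labels are 1 on
#' average.
#'
#' @param n Number of samples (default 40).
#' @param seed Optional integer seed.
#' @param p_noise Number of pure-noise columns (default 610).
#' @return A list of class `sim_layers`: `X` (n x p matrix with column names
#'   `x1..xp`), `Y` (0/1 vector), `layout` (tibble with `index`,
#'   `feature_id`, `tag`, `layer`), `seed`, and `truth` (indices of the
#'   layer-1 variables).
#' @export
simulate_layers <- function(n = 40L, seed = NULL, p_noise = 610L) {
  n <- as.integer(n)
  if (n < 10L) stop("`n` must be at least 10", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)

  Y <- stats::rbinom(n, 1L, 0.4)
  L1 <- matrix(0, n, 30L)
  for (p in 1:4) L1[, p] <- stats::runif(n) + 0.8 - 2 * Y
  for (p in 5:9) L1[, p] <- stats::runif(n) - 1.2 + 2 * Y
  Sigma <- matrix(c(12, 10, 8, 10, 12, 10, 8, 10, 12), 3, 3)
  Rchol <- chol(Sigma)
  for (p in seq(10L, 28L, by = 3L)) {
    Z <- matrix(stats::rnorm(n * 3L), n, 3L)
    L1[, p:(p + 2L)] <- Z %*% Rchol + outer(Y, c(1, 2, 3))
  }

  L2 <- decompose_layer(L1)    # 90 children of the 30 layer-1 parents
  L3 <- decompose_layer(L2)    # 270 children of the 90 layer-2 parents
  noise <- matrix(stats::rnorm(n * p_noise), n, p_noise)

  X <- cbind(L1, L2, L3, noise)
  colnames(X) <- paste0("x", seq_len(ncol(X)))

  tags <- c(
    rep("strong_pos", 4), rep("strong_neg", 5), rep("group", 21),
    rep("layer2", ncol(L2)), rep("layer3", ncol(L3)), rep("noise", p_noise)
  )
  layers <- c(rep("layer1", 30L), rep("layer2", ncol(L2)),
              rep("layer3", ncol(L3)), rep("noise", p_noise))
  layout <- tibble::tibble(
    index = seq_len(ncol(X)),
    feature_id = colnames(X),
    tag = tags,
    layer = layers
  )
  structure(
    list(X = X, Y = Y, layout = layout, seed = seed, truth = 1:30),
    class = "sim_layers"
  )
}

# Split every column of `parents` into a triple of children: weights
# u_i / sum(u) drawn once per parent, per-sample noise eps ~ N(0, |x|/10)
# (sd reading of the noise scale), children w_i * (x + eps).
decompose_layer <- function(parents) {
  n <- nrow(parents)
  q <- ncol(parents)
  out <- matrix(0, n, 3L * q)
  for (j in seq_len(q)) {
    u <- stats::runif(3L)
    w <- u / sum(u)
    eps <- stats::rnorm(n, mean = 0, sd = abs(parents[, j]) / 10)
    base <- parents[, j] + eps
    out[, (3L * j - 2L):(3L * j)] <- base %o% w
  }
  out
}

#' @export
print.sim_layers <- function(x, ...) {
  cat("<sim_layers> ", nrow(x$X), " x ", ncol(x$X),
      " simulated dataset; ", sum(x$Y), " of ", length(x$Y),
      " labels are 1\n", sep = "")
  invisible(x)
}

#' Tally selected variables by simulation layer
#'
#' @param selected Integer indices of selected variables.
#' @param layout The `layout` tibble of a [simulate_layers()] dataset (or
#'   any tibble with `index` and `layer` columns).
#' @return A tibble with one row per layer (`layer1`, `layer2`, `layer3`,
#'   `noise`) and the count of selected variables in it.
#' @export
layer_counts <- function(selected, layout) {
  selected <- as.integer(selected)
  if (length(selected) > 0 && !all(selected %in% layout$index)) {
    bad <- setdiff(selected, layout$index)
    stop("selected index not in layout: ", paste(utils::head(bad, 5), collapse = ", "),
         call. = FALSE)
  }
  lv <- c("layer1", "layer2", "layer3", "noise")
  hit <- layout$layer[match(selected, layout$index)]
  tibble::tibble(
    layer = lv,
    count = as.integer(table(factor(hit, levels = lv)))
  )
}
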