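# Independent oracles and small data builders used across the suite.

# random centered predictor/response pair
rand_centered <- function(n, p, seed) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p)
  y <- rnorm(n)
  list(X = scale(X, scale = FALSE), y = y - mean(y))
}

# Classical NIPALS PLS1 (projection deflation, unnormalised scores),
# written independently of the package internals. Returns scores normalised
# to unit length for comparison up to column sign.
nipals_pls1_oracle <- function(X, y, A) {
  E <- X
  Tm <- matrix(0, nrow(X), A)
  for (a in seq_len(A)) {
    w <- crossprod(E, y)
    w <- w / sqrt(sum(w^2))
    t <- drop(E %*% w)
    p <- crossprod(E, t) / sum(t^2)
    E <- E - t %*% t(p)
    Tm[, a] <- t / sqrt(sum(t^2))
  }
  Tm
}

# Benjamini-Hochberg step-up by hand: largest k with p_(k) <= k*q/m,
# reject everything at or below that order statistic.
bh_stepup_oracle <- function(p, q) {
  m <- length(p)
  ord <- order(p)
  ok <- which(p[ord] <= seq_len(m) * q / m)
  if (length(ok) == 0L) return(integer(0))
  sort(ord[seq_len(max(ok))])
}

# least-squares projection of y onto the column space of X via the normal
# equations (full-column-rank case only)
normal_eq_projection <- function(X, y) {
  drop(X %*% solve(crossprod(X), crossprod(X, y)))
}

# agreement of two score matrices up to per-column sign
max_score_diff <- function(T1, T2) {
  max(vapply(seq_len(ncol(T1)), function(j) {
    min(max(abs(T1[, j] - T2[, j])), max(abs(T1[, j] + T2[, j])))
  }, numeric(1)))
}

# minimum-norm least squares through the pseudoinverse (independent of the
# package's own SVD solver)
minimum_norm_ls_oracle <- function(X, y) drop(MASS::ginv(X) %*% y)
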