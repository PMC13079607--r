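# Independent reference implementations used as oracles. These are written
# as direct scans / numerical integrations, deliberately sharing no code
# with the package internals.

# Exhaustive run-walking extrema scan: plateaus collapse to their first
# index; a boundary is a valley when the series moves upward away from it.
brute_extrema <- function(x) {
  n <- length(x)
  peaks <- integer(0)
  valleys <- integer(0)
  i <- 1L
  while (i <= n) {
    j <- i
    while (j < n && x[j + 1] == x[i]) j <- j + 1L
    left <- if (i == 1L) NA_real_ else x[i - 1L]
    right <- if (j == n) NA_real_ else x[j + 1L]
    if (!is.na(left) && !is.na(right)) {
      if (x[i] > left && x[i] > right) peaks <- c(peaks, i)
      if (x[i] < left && x[i] < right) valleys <- c(valleys, i)
    } else if (is.na(left) && !is.na(right)) {
      if (right > x[i]) valleys <- c(valleys, i)
    } else if (is.na(right) && !is.na(left)) {
      if (left > x[i]) valleys <- c(valleys, i)
    }
    i <- j + 1L
  }
  list(peaks = peaks, valleys = valleys)
}

# Coarse-then-refined grid search of the Gamma log-likelihood surface.
grid_gamma_mle <- function(x, levels = 3, span = 4, pts = 41) {
  a0 <- mean(x)^2 / var(x)
  b0 <- var(x) / mean(x)
  best <- c(a0, b0)
  width <- span
  for (l in seq_len(levels)) {
    as <- exp(seq(log(best[1] / width), log(best[1] * width), length.out = pts))
    bs <- exp(seq(log(best[2] / width), log(best[2] * width), length.out = pts))
    ll <- outer(as, bs, function(a, b) {
      vapply(seq_along(a), function(i) {
        sum(dgamma(x, shape = a[i], scale = b[i], log = TRUE))
      }, numeric(1))
    })
    idx <- arrayInd(which.max(ll), dim(ll))
    best <- c(as[idx[1]], bs[idx[2]])
    width <- width^(1 / 3)
  }
  list(shape = best[1], scale = best[2],
       resolution = best * (width^(1 / 2) - 1))
}

# Ellipse-axis oracle for the Poincare descriptors: project the lag-1
# scatter onto the two 45-degree ellipse axis directions and take the
# population SDs of the projections.
poincare_oracle <- function(x) {
  n <- length(x)
  p <- cbind(x[-n], x[-1])
  u1 <- c(-1, 1) / sqrt(2)   # short axis direction
  u2 <- c(1, 1) / sqrt(2)    # long axis direction
  sd_pop <- function(v) sqrt(mean((v - mean(v))^2))
  c(sd1 = sd_pop(p %*% u1), sd2 = sd_pop(p %*% u2))
}

# Exact Wasserstein-1 via the quantile-function integral: both empirical
# quantile functions are step functions with breakpoints on the grid
# k/(n*m), so midpoint evaluation on that grid integrates exactly.
emd_quantile_oracle <- function(x, y) {
  n <- length(x)
  m <- length(y)
  steps <- n * m
  p <- (seq_len(steps) - 0.5) / steps
  qx <- quantile(x, probs = p, type = 1, names = FALSE)
  qy <- quantile(y, probs = p, type = 1, names = FALSE)
  mean(abs(qx - qy))
}

# Random series mixing smooth, noisy, and tie-heavy (plateau-forcing)
# cases for property tests.
random_series <- function(n, kind = c("walk", "smooth", "ties")) {
  kind <- match.arg(kind)
  switch(kind,
    walk = cumsum(rnorm(n)),
    smooth = sin(seq(0, 6 * pi, length.out = n)) + rnorm(n, 0, 0.2),
    ties = as.numeric(sample(1:5, n, replace = TRUE)))
}
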