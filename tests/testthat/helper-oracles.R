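# Independent oracles used across the suite. These are deliberately written
# in the most literal way possible (explicit loops, regression residuals,
# grid search) so they share no code path with the package implementation.

# Deng grey relational analysis by explicit looping over sequences and
# positions: mean-normalize, per-position absolute differences, global
# extrema, coefficient ratio, arithmetic-mean grade.
brute_force_gra <- function(standard, inspected, p = 0.5) {
  x0 <- standard / mean(standard)
  m <- ncol(inspected)
  n <- length(standard)
  norm <- vector("list", m)
  for (i in seq_len(m)) norm[[i]] <- inspected[, i] / mean(inspected[, i])
  deltas <- matrix(NA_real_, m, n)
  for (i in seq_len(m)) {
    for (k in seq_len(n)) {
      deltas[i, k] <- abs(x0[k] - norm[[i]][k])
    }
  }
  d_min <- min(deltas)
  d_max <- max(deltas)
  coefs <- matrix(NA_real_, m, n)
  for (i in seq_len(m)) {
    for (k in seq_len(n)) {
      coefs[i, k] <- if (d_max == 0) 1 else {
        (d_min + p * d_max) / (deltas[i, k] + p * d_max)
      }
    }
  }
  grades <- numeric(m)
  for (i in seq_len(m)) grades[i] <- sum(coefs[i, ]) / n
  list(coefficients = coefs, grades = grades, d_min = d_min, d_max = d_max)
}

# KMO through explicit partial-correlation regressions: realize the
# correlation matrix as data (MASS::mvrnorm with empirical = TRUE imposes it
# exactly), then compute each partial correlation as the correlation of the
# two regression residuals given all other variables.
kmo_regression_oracle <- function(R) {
  p <- ncol(R)
  X <- MASS::mvrnorm(n = 10 * p + 50, mu = rep(0, p), Sigma = R, empirical = TRUE)
  r2_sum <- 0
  q2_sum <- 0
  for (i in seq_len(p)) {
    for (j in seq_len(p)) {
      if (i == j) next
      r2_sum <- r2_sum + R[i, j]^2
      others <- setdiff(seq_len(p), c(i, j))
      if (length(others) == 0) {
        q <- stats::cor(X[, i], X[, j])
      } else {
        ri <- stats::resid(stats::lm(X[, i] ~ X[, others]))
        rj <- stats::resid(stats::lm(X[, j] ~ X[, others]))
        q <- stats::cor(ri, rj)
      }
      q2_sum <- q2_sum + q^2
    }
  }
  r2_sum / (r2_sum + q2_sum)
}

# Planar grid search over rotation angles for 2-component varimax: the
# global optimum over orthogonal 2x2 rotations (including column sign flips,
# which leave the criterion unchanged) to grid resolution.
varimax_grid_oracle <- function(L, kaiser_normalize = FALSE, step = 0.001) {
  angles <- seq(0, pi / 2, by = step)
  best <- -Inf
  for (a in angles) {
    Rot <- matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)
    val <- varimax_criterion(L %*% Rot, kaiser_normalize = kaiser_normalize)
    if (val > best) best <- val
  }
  best
}

# A random correlation matrix via the empirical correlation of a gaussian
# data matrix (always positive definite when n > p).
random_correlation <- function(p, n = 20 * p) {
  stats::cor(matrix(stats::rnorm(n * p), n, p))
}

random_moment_spec <- function(m) {
  moment_spec(
    tibble::tibble(
      indicator = paste0("ind", seq_len(m)),
      mean = stats::runif(m, -10, 100),
      sd = stats::runif(m, 0.1, 20),
      r = stats::runif(m, -0.9, 0.9)
    ),
    criterion_name = "crit",
    criterion_mean = stats::runif(1, 1, 10),
    criterion_sd = stats::runif(1, 0.1, 3)
  )
}
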