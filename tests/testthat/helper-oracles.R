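# Independent brute-force oracles used to validate the implementation.
# These are written from first principles and share no code with R/.

# Pearson correlation from raw sums
naive_pearson <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  sxx <- sum(x * x); syy <- sum(y * y); sxy <- sum(x * y)
  num <- n * sxy - sx * sy
  den <- sqrt(n * sxx - sx^2) * sqrt(n * syy - sy^2)
  if (den == 0) return(NA_real_)
  num / den
}

# per-window, per-lag cross-correlation by explicit loops
naive_wcc <- function(x, y, fps, window_s, step_s, max_lag_s, lag_step = 1L) {
  n <- length(x)
  w <- round(window_s * fps)
  step <- round(step_s * fps)
  maxlag <- round(max_lag_s * fps)
  lags <- seq(-maxlag, maxlag, by = lag_step)
  starts <- seq(1, n - w + 1, by = step)
  r <- matrix(NA_real_, length(starts), length(lags))
  for (wi in seq_along(starts)) {
    for (li in seq_along(lags)) {
      l <- lags[li]
      xs <- c(); ys <- c()
      for (t in starts[wi]:(starts[wi] + w - 1)) {
        if (t + l >= starts[wi] && t + l <= starts[wi] + w - 1) {
          xs <- c(xs, x[t]); ys <- c(ys, y[t + l])
        }
      }
      if (length(xs) >= 4) r[wi, li] <- naive_pearson(xs, ys)
    }
  }
  r
}

# changed-pixel count by an explicit per-pixel double loop
naive_frame_diff <- function(prev, curr, x0, y0, w, h, threshold) {
  count <- 0L
  for (row in (y0 + 1):(y0 + h)) {
    for (col in (x0 + 1):(x0 + w)) {
      if (abs(curr[row, col] - prev[row, col]) > threshold) count <- count + 1L
    }
  }
  count
}

# Mann-Whitney U (for sample a) by direct pair counting
naive_u <- function(a, b) {
  u <- 0
  for (x in a) for (y in b) u <- u + (x > y) + 0.5 * (x == y)
  u
}

# exact one-sided P(U >= u_obs) by enumerating every group assignment
naive_u_p_greater <- function(a, b) {
  pooled <- c(a, b)
  n1 <- length(a)
  u_obs <- naive_u(a, b)
  splits <- combn(length(pooled), n1)
  us <- apply(splits, 2, function(idx) naive_u(pooled[idx], pooled[-idx]))
  mean(us >= u_obs - 1e-9)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# small bursty nonnegative fixture series
fixture_series <- function(n, seed, fps = 5) {
  set.seed(seed)
  v <- pmax(0, cumsum(rnorm(n, 0, 1)) + rexp(n) * rbinom(n, 1, 0.2))
  motion_energy_series(v, fps)
}
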