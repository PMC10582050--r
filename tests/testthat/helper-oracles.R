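# Independent oracle implementations used across the suite. These are kept
# deliberately naive (loops, closed forms) and must never call package code.

# Textbook Hedges' d with the 1 - 3/(4m - 1) correction, written directly
# from the defining formulas.
oracle_hedges <- function(mean_low, sd_low, n_low, mean_high, sd_high, n_high) {
  m <- n_low + n_high - 2
  s_pooled <- sqrt(((n_low - 1) * sd_low^2 + (n_high - 1) * sd_high^2) / m)
  d <- (1 - 3 / (4 * m - 1)) * (mean_high - mean_low) / s_pooled
  list(estimate = d,
       variance = 1 / n_low + 1 / n_high + d^2 / (2 * (n_low + n_high)))
}

# Log response ratio and its variance from the defining formulas.
oracle_rr <- function(p_low, n_low, p_high, n_high) {
  list(estimate = log(p_low) - log(p_high),
       variance = (1 - p_low) / (n_low * p_low) +
                  (1 - p_high) / (n_high * p_high))
}

# Brute-force per-pixel NDVI metrics: explicit loops over months and pixels,
# population SDs throughout.
oracle_ndvi <- function(month_matrices) {
  n <- length(month_matrices)
  mu <- numeric(n); sig <- numeric(n)
  for (i in seq_len(n)) {
    v <- as.vector(month_matrices[[i]])
    m <- 0
    for (x in v) m <- m + x
    m <- m / length(v)
    s <- 0
    for (x in v) s <- s + (x - m)^2
    mu[i] <- m
    sig[i] <- sqrt(s / length(v))
  }
  a <- mean(mu)
  list(ndvi_a = a,
       ndvi_sp = mean(sig / mu),
       ndvi_tm = sqrt(mean((mu - a)^2)) / a)
}

# Grid-search ML oracle: profile log-likelihood evaluated on a dense tau2
# grid (step 1e-4 over [0, 2]), vectorized over the grid for speed but
# algebraically independent of the package's optimizer. Supports intercept-
# only and intercept + one moderator designs.
oracle_grid_loglik <- function(yi, vi, x = NULL, grid = seq(0, 2, by = 1e-4)) {
  k <- length(yi)
  V <- outer(grid, vi, "+")            # G x k total variances
  W <- 1 / V
  Y <- matrix(yi, nrow(W), k, byrow = TRUE)
  if (is.null(x)) {
    beta <- rowSums(W * Y) / rowSums(W)
    res2 <- (Y - beta)^2
  } else {
    Xm <- matrix(x, nrow(W), k, byrow = TRUE)
    Sw <- rowSums(W); Sx <- rowSums(W * Xm); Sy <- rowSums(W * Y)
    Sxx <- rowSums(W * Xm^2); Sxy <- rowSums(W * Xm * Y)
    det <- Sw * Sxx - Sx^2
    b0 <- (Sxx * Sy - Sx * Sxy) / det
    b1 <- (Sw * Sxy - Sx * Sy) / det
    res2 <- (Y - b0 - b1 * Xm)^2
  }
  ll <- -0.5 * rowSums(log(2 * pi * V)) - 0.5 * rowSums(W * res2)
  list(logLik = max(ll), tau2 = grid[which.max(ll)])
}
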