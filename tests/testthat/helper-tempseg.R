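# shared fixtures, all built in code

# n x k data matrix whose SAMPLE correlation matrix equals sigma exactly:
# columns of an orthonormal, mean-zero basis mixed by chol(sigma)
make_exact_cor_data <- function(n, sigma, seed = 1) {
  k <- ncol(sigma)
  withr_seed <- function(code) { set.seed(seed); code }
  z <- withr_seed(matrix(rnorm(n * k), n, k))
  q <- qr.Q(qr(cbind(1, z)))[, 2:(k + 1)]
  q %*% chol(sigma)
}

# brute-force semipartial oracle: explicit normal-equations OLS residual
# of x on covariates, then plain correlation with y
semipartial_oracle <- function(x, y, z) {
  d <- cbind(1, as.matrix(z))
  beta <- solve(t(d) %*% d, t(d) %*% x)
  res <- x - d %*% beta
  cor(as.numeric(res), y)
}

# dense 3-D grid-search oracle for the two-limbed least-squares objective
# (log10 scale), independent of the package's profiled fitter
tl_grid_oracle <- function(durations, thresholds, n_grid = 100,
                           s_max = 10) {
  lx <- log10(durations); ly <- log10(thresholds)
  lkb <- log10(c(0.5 * min(durations), 2 * max(durations)))
  lks <- seq(lkb[1], lkb[2], length.out = n_grid)
  lts <- seq(min(ly) - 0.3, max(ly) + 0.3, length.out = n_grid)
  ss <- seq(0, s_max, length.out = n_grid)
  best <- Inf
  for (lk in lks) {
    u <- pmax(0, lk - lx)
    for (s in ss) {
      base <- ly - s * u
      v <- min(rowSums(outer(lts, base, function(a, b) (b - a)^2)))
      if (v < best) best <- v
    }
  }
  best
}

# two-limbed parameters whose noiseless curve stays below the coherence
# ceiling on the default duration grid
draw_feasible_tl <- function(grid, k_range = c(0.05, 0.15),
                             t_range = c(10, 40), s_range = c(0.7, 2)) {
  repeat {
    k <- runif(1, k_range[1], k_range[2])
    tt <- runif(1, t_range[1], t_range[2])
    s <- runif(1, s_range[1], s_range[2])
    if (two_limbed(min(grid), k, tt, s) <= 95) return(c(k = k, t = tt,
                                                        s = s))
  }
}

# toroidal displacement helper mirroring the geometry of the dot field
wrap_delta <- function(p2, p1, w) (p2 - p1 + w / 2) %% w - w / 2

# small cached copy of the calibrated default configuration (calibration
# itself is memoized inside the package)
calibrated_config <- function() default_calibrated_config(calibrate = TRUE)
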