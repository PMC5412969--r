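#' Two-limbed threshold versus segment-duration function
#'
#' The broken-stick curve used to characterize coherence thresholds as a
#' function of segment duration: on log-log axes a descending limb of
#' slope `-s` below the knee-point `k`, and a flat asymptote `t` above
#' it,
#' \deqn{y(x) = t (k/x)^s \;\; (x < k), \qquad y(x) = t \;\; (x \ge k),}
#' continuous at `x = k` and monotone non-increasing in `x`. `k` is the
#' segment duration above which performance no longer improves, `t` the
#' coherence threshold at asymptote, and `s` the slope of the descending
#' limb in log-log units.
#'
#' @param x segment duration(s), seconds, > 0.
#' @param k knee-point, seconds, > 0.
#' @param t asymptotic threshold, percent coherence, > 0.
#' @param s descending-limb slope, >= 0.
#' @return predicted threshold(s), percent coherence.
#' @export
two_limbed <- function(x, k, t, s) {
  if (any(x <= 0) || k <= 0 || t <= 0) {
    stop("`x`, `k` and `t` must be positive", call. = FALSE)
  }
  if (s < 0) stop("`s` must be non-negative", call. = FALSE)
  ifelse(x < k, t * (k / x)^s, t)
}

# sum of squared log10 residuals for given parameters
.tl_sse <- function(lx, ly, lk, lt, s) {
  pred <- lt + s * pmax(0, lk - lx)
  sum((ly - pred)^2)
}

# for fixed knee the model is linear in (log10 t, s): closed-form
# least-squares with the slope constrained to [0, s_max]
.tl_profile_k <- function(lx, ly, lk, s_max = 10) {
  u <- pmax(0, lk - lx)
  su <- sum((u - mean(u))^2)
  if (su < 1e-14) {
    s <- 0
  } else {
    s <- sum((u - mean(u)) * (ly - mean(ly))) / su
    s <- min(max(s, 0), s_max)
  }
  lt <- mean(ly) - s * mean(u)
  list(lk = lk, lt = lt, s = s, sse = .tl_sse(lx, ly, lk, lt, s))
}

#' Fit the two-limbed curve to threshold data
#'
#' Least-squares fit of [two_limbed()] on the log10 scale (log10
#' threshold against log10 duration), the natural scale for a function
#' that is piecewise linear in log-log coordinates. The fit combines a
#' profiled knee search (for fixed `k` the remaining parameters have a
#' closed-form solution) over a dense log-spaced grid with
#' Levenberg-Marquardt polishing ([minpack.lm::nlsLM]) from multiple
#' starts (the profile optimum plus each interior grid duration); the
#' best objective wins and ties go to the smallest knee. Deterministic
#' given the data.
#'
#' @param durations segment durations, seconds, strictly increasing, > 0
#'   (>= 4 points).
#' @param thresholds coherence thresholds, percent, in (0, 100].
#' @param k_bounds knee search range; default
#'   `c(0.5 * min(durations), 2 * max(durations))`.
#' @param s_max upper bound on the slope.
#' @return an object of class `two_limbed_fit`: `k`, `t`, `s`,
#'   `r_squared` (computed on the fitted log10 scale), `sse`,
#'   `residuals` (log10 scale), `converged`, and the data.
#' @export
fit_two_limbed <- function(durations, thresholds, k_bounds = NULL,
                           s_max = 10) {
  if (length(durations) != length(thresholds)) {
    stop("`durations` and `thresholds` must have equal length",
         call. = FALSE)
  }
  if (length(durations) < 4) {
    stop("at least 4 points are needed to fit 3 free parameters",
         call. = FALSE)
  }
  if (any(durations <= 0) || is.unsorted(durations, strictly = TRUE)) {
    stop("`durations` must be positive and strictly increasing",
         call. = FALSE)
  }
  if (any(thresholds <= 0 | thresholds > 100)) {
    stop("`thresholds` must lie in (0, 100]", call. = FALSE)
  }
  lx <- log10(durations)
  ly <- log10(thresholds)
  if (is.null(k_bounds)) {
    k_bounds <- c(0.5 * min(durations), 2 * max(durations))
  }
  lkb <- log10(k_bounds)

  # stage 1: coarse profiled knee grid
  lk_grid <- seq(lkb[1], lkb[2], length.out = 300)
  prof <- lapply(lk_grid, function(lk) .tl_profile_k(lx, ly, lk, s_max))
  sse <- vapply(prof, `[[`, numeric(1), "sse")
  i <- which.min(sse)
  # stage 2: refined grid around the coarse optimum
  hw <- diff(lkb) / 299
  lk_fine <- seq(max(lkb[1], lk_grid[i] - hw),
                 min(lkb[2], lk_grid[i] + hw), length.out = 120)
  proff <- lapply(lk_fine, function(lk) .tl_profile_k(lx, ly, lk, s_max))
  ssef <- vapply(proff, `[[`, numeric(1), "sse")
  best <- proff[[which.min(ssef)]]

  candidates <- list(best)
  # Levenberg-Marquardt polish from multiple starts
  s0_global <- max(0, min(s_max, (ly[1] - ly[length(ly)]) /
                            (lx[length(lx)] - lx[1])))
  starts <- c(list(c(best$lk, best$lt, best$s)),
              lapply(lx[-c(1, length(lx))], function(lk0) {
                c(lk0, min(ly), s0_global)
              }))
  dat <- data.frame(lx = lx, ly = ly)
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        ly ~ lt + s * pmax(0, lk - lx), data = dat,
        start = list(lk = st[1], lt = st[2], s = st[3]),
        lower = c(lkb[1], -3, 0), upper = c(lkb[2], 2, s_max),
        control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-15,
                                             ptol = 1e-15)),
      error = function(e) NULL, warning = function(w) NULL)
    if (!is.null(fit)) {
      cf <- stats::coef(fit)
      candidates <- c(candidates, list(
        list(lk = cf[["lk"]], lt = cf[["lt"]], s = cf[["s"]],
             sse = .tl_sse(lx, ly, cf[["lk"]], cf[["lt"]], cf[["s"]]))))
    }
  }
  # derivative-free polish as backstop around the kink, restarted from
  # the best candidate so far
  obj <- function(p) {
    if (p[1] < lkb[1] || p[1] > lkb[2] || p[3] < 0 || p[3] > s_max) {
      return(.Machine$double.xmax)
    }
    .tl_sse(lx, ly, p[1], p[2], p[3])
  }
  for (pass in 1:2) {
    sses0 <- vapply(candidates, `[[`, numeric(1), "sse")
    b0 <- candidates[[which.min(sses0)]]
    nm <- tryCatch(
      optim(c(b0$lk, b0$lt, b0$s), obj, method = "Nelder-Mead",
            control = list(maxit = 1000, reltol = 1e-15)),
      error = function(e) NULL)
    if (!is.null(nm) && nm$value < .Machine$double.xmax) {
      candidates <- c(candidates, list(
        list(lk = nm$par[1], lt = nm$par[2], s = nm$par[3],
             sse = nm$value)))
    }
  }

  sses <- vapply(candidates, `[[`, numeric(1), "sse")
  ks <- vapply(candidates, `[[`, numeric(1), "lk")
  # ties (within numerical noise) go to the smallest knee
  eligible <- which(sses <= min(sses) + 1e-12)
  pick <- candidates[[eligible[which.min(ks[eligible])]]]

  pred <- pick$lt + pick$s * pmax(0, pick$lk - lx)
  res <- ly - pred
  r2 <- r_squared(ly, pred)
  structure(list(k = 10^pick$lk, t = 10^pick$lt, s = pick$s,
                 r_squared = r2, sse = pick$sse, residuals = res,
                 converged = is.finite(pick$sse),
                 durations = durations, thresholds = thresholds),
            class = "two_limbed_fit")
}

#' @export
print.two_limbed_fit <- function(x, ...) {
  cat(sprintf(
    "<two_limbed_fit> k = %.4g s, t = %.4g %%, s = %.3g, R^2 = %.3f\n",
    x$k, x$t, x$s, x$r_squared))
  invisible(x)
}

#' Coefficient of determination
#'
#' `1 - SS_res / SS_tot`, computed on whatever scale the inputs are on
#' (curve fits use log10 thresholds). If the observations have zero
#' variance the statistic is 1 when the residuals are also (numerically)
#' zero, and `NA` with a warning otherwise.
#'
#' @param observed,predicted numeric vectors of equal length >= 2.
#' @return R-squared value (<= 1).
#' @export
r_squared <- function(observed, predicted) {
  if (length(observed) != length(predicted) || length(observed) < 2) {
    stop("`observed` and `predicted` must have equal length >= 2",
         call. = FALSE)
  }
  ss_res <- sum((observed - predicted)^2)
  ss_tot <- sum((observed - mean(observed))^2)
  if (ss_tot == 0) {
    if (ss_res < 1e-20) return(1)
    warning("zero total variance with nonzero residuals: R^2 undefined")
    return(NA_real_)
  }
  1 - ss_res / ss_tot
}
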