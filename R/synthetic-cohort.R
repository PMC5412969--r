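#' Synthetic cohort configuration
#'
#' Describes the latent model behind a synthetic participant cohort: a
#' Gaussian copula in which a latent reading ability and a latent
#' nonverbal ability drive, respectively, the three reading-test scores
#' (single-factor model with per-test loadings) and the IQ score, and
#' each visual outcome is a linear combination of the two latents plus
#' independent noise, pushed through a per-outcome marginal transform
#' (log-normal for the skewed outcomes - motion acuity, both knees, both
#' slopes - and normal for form acuity and the two asymptotes). Gender
#' is assigned independently of all latents (a fixed number of men per
#' cohort).
#'
#' @param n cohort size.
#' @param n_male number of men.
#' @param reading_loadings factor loadings of the three reading tests on
#'   the latent reading ability (NART, TOWRE Sight Word Efficiency,
#'   TOWRE Phonemic Decoding Efficiency).
#' @param reading_paths named vector: latent path from reading ability to
#'   each of the eight visual outcomes.
#' @param iq_paths named vector: latent path from nonverbal ability to
#'   each outcome (nonzero for the two asymptotes).
#' @param marginals named list of per-outcome marginal transforms
#'   (`list(dist = "lnorm", meanlog=, sdlog=)` or
#'   `list(dist = "norm", mean=, sd=, lo=, hi=)`).
#' @param targets data frame of calibration targets (outcome, target
#'   coefficient, correlation method) for the reading-composite
#'   semipartials.
#' @param iq_targets named vector of IQ-semipartial targets for the two
#'   asymptotes.
#' @param reading_scales list of raw-score scales (mean, sd, lo, hi) for
#'   the three tests.
#' @param iq_mean,iq_sd observed IQ scale.
#' @param age_mean,age_sd age distribution, years (descriptive only;
#'   never analysed).
#' @param grid segment-duration grid for threshold-curve synthesis,
#'   seconds.
#' @param noise_sigma log-normal threshold noise (sd of log10 deviates is
#'   `noise_sigma / log(10)`; multiplicative sd `noise_sigma` on the
#'   natural-log scale).
#' @param calibrated logical flag set by [calibrate_cohort_paths()].
#' @return an object of class `cohort_config`.
#' @export
cohort_config <- function(n = 38L, n_male = 6L,
                          reading_loadings = c(nart = 0.72,
                                               towre_swe = 0.87,
                                               towre_pde = 0.85),
                          reading_paths = NULL,
                          iq_paths = NULL,
                          marginals = default_marginals(),
                          targets = default_reading_targets(),
                          iq_targets = c(motion_asymptote_pct = -0.46,
                                         form_asymptote_pct = -0.48),
                          reading_scales = list(
                            nart = c(mean = 35, sd = 7, lo = 0, hi = 50),
                            towre_swe = c(mean = 80, sd = 10, lo = 0,
                                          hi = 104),
                            towre_pde = c(mean = 40, sd = 9, lo = 0,
                                          hi = 63)),
                          iq_mean = 100, iq_sd = 15,
                          age_mean = 20.35, age_sd = 2.82 / 12,
                          grid = 10^seq(log10(0.03), log10(0.215),
                                        length.out = 5),
                          noise_sigma = 0.05,
                          calibrated = FALSE) {
  outs <- .cohort_outcomes()
  if (is.null(reading_paths)) {
    reading_paths <- setNames(rep(0, length(outs)), outs)
  }
  if (is.null(iq_paths)) {
    iq_paths <- setNames(rep(0, length(outs)), outs)
  }
  stopifnot(n >= 4, n_male >= 0, n_male <= n,
            length(reading_loadings) == 3,
            all(reading_loadings > 0 & reading_loadings < 1),
            all(outs %in% names(reading_paths)),
            all(outs %in% names(iq_paths)))
  tot <- reading_paths[outs]^2 + iq_paths[outs]^2
  if (any(tot >= 1)) {
    stop("infeasible paths: implied latent covariance not positive ",
         "semidefinite (a^2 + b^2 >= 1 for some outcome)", call. = FALSE)
  }
  structure(list(n = as.integer(n), n_male = as.integer(n_male),
                 reading_loadings = reading_loadings,
                 reading_paths = reading_paths[outs],
                 iq_paths = iq_paths[outs],
                 marginals = marginals, targets = targets,
                 iq_targets = iq_targets,
                 reading_scales = reading_scales,
                 iq_mean = iq_mean, iq_sd = iq_sd,
                 age_mean = age_mean, age_sd = age_sd,
                 grid = grid, noise_sigma = noise_sigma,
                 calibrated = calibrated),
            class = "cohort_config")
}

#' Default marginal transforms for the visual outcomes
#'
#' Motion acuity, both knee-points and both slopes are right-skewed
#' (log-normal marginals), so they fail the Shapiro-Wilk gate in most
#' cohorts; form acuity and the two asymptotic thresholds are normal.
#' Locations are plausible task values: acuities of a few tens of
#' milliseconds, knees near the middle of the 0.03-0.215 s duration
#' grid, asymptotic thresholds of 20-25% coherence, log-log slopes
#' around 1.
#'
#' @return named list of marginal descriptors.
#' @export
default_marginals <- function() {
  list(
    motion_acuity_s = list(dist = "lnorm", meanlog = log(0.045),
                           sdlog = 0.5),
    motion_knee_s = list(dist = "lnorm", meanlog = log(0.075),
                         sdlog = 0.45),
    motion_asymptote_pct = list(dist = "norm", mean = 20, sd = 6,
                                lo = 2, hi = 95),
    motion_slope = list(dist = "lnorm", meanlog = log(1.2), sdlog = 0.5),
    form_acuity_s = list(dist = "norm", mean = 0.055, sd = 0.012,
                         lo = 0.012, hi = 0.4),
    form_knee_s = list(dist = "lnorm", meanlog = log(0.08), sdlog = 0.45),
    form_asymptote_pct = list(dist = "norm", mean = 25, sd = 7,
                              lo = 2, hi = 95),
    form_slope = list(dist = "lnorm", meanlog = log(1.3), sdlog = 0.5)
  )
}

#' Calibration targets for the reading-composite semipartials
#'
#' The observable semipartial correlation (after PCA compositing,
#' normality gating and covariate partialling) that each visual outcome
#' should show with the composite reading score, and the correlation
#' method the gate is expected to select for it.
#'
#' @return data frame with columns `outcome`, `target`, `method`.
#' @export
default_reading_targets <- function() {
  data.frame(
    outcome = .cohort_outcomes(),
    target = c(-0.46, 0.07, -0.33, 0.26, -0.40, -0.04, -0.23, 0.27),
    method = c("spearman", "spearman", "pearson", "spearman",
               "pearson", "spearman", "pearson", "spearman")
  )
}

# correlation between the PC1 composite and the latent reading ability,
# implied by the single-factor loadings (population value)
.composite_reliability <- function(loadings) {
  l <- unname(loadings)
  sigma <- tcrossprod(l) + diag(1 - l^2)
  e <- eigen(sigma, symmetric = TRUE)
  v1 <- e$vectors[, 1]
  if (sum(v1) < 0) v1 <- -v1
  sum(v1 * l) / sqrt(e$values[1])
}

# analytic initial paths: invert the Spearman(latent Pearson) map for
# rank-gated outcomes and divide by the composite reliability
.analytic_paths <- function(config) {
  rho_c <- .composite_reliability(config$reading_loadings)
  tg <- config$targets
  a <- setNames(numeric(nrow(tg)), tg$outcome)
  for (i in seq_len(nrow(tg))) {
    rho <- if (tg$method[i] == "spearman") {
      2 * sin(pi * tg$target[i] / 6)
    } else {
      tg$target[i]
    }
    a[tg$outcome[i]] <- rho / rho_c
  }
  b <- setNames(rep(0, length(.cohort_outcomes())), .cohort_outcomes())
  b[names(config$iq_targets)] <- config$iq_targets
  list(reading = a, iq = b)
}

#' Calibrate latent paths to the observable targets
#'
#' The semipartial correlations measured by [analyze_cohort()] are
#' attenuated relative to the latent paths (composite reliability,
#' rank-transform of the Gaussian copula, finite-sample residualization,
#' gate mixing), so the paths are solved numerically: starting from
#' analytic values, each path is adjusted by the replicate-averaged
#' discrepancy between the observed gated coefficient and its target,
#' scaled by the composite reliability. Uses a fixed internal seed, so
#' the calibrated configuration is fully deterministic.
#'
#' @param config a [cohort_config()] whose `targets` should be matched.
#' @param n_reps replicate cohorts per iteration.
#' @param iters correction iterations.
#' @param internal_seed seed of the calibration stream (independent of
#'   any analysis seed).
#' @return the calibrated `cohort_config`.
#' @export
calibrate_cohort_paths <- function(config, n_reps = 300, iters = 2,
                                   internal_seed = 20170501) {
  paths <- .analytic_paths(config)
  config$reading_paths <- paths$reading
  config$iq_paths <- paths$iq
  rho_c <- .composite_reliability(config$reading_loadings)
  outs <- .cohort_outcomes()
  iq_outs <- names(config$iq_targets)
  tg <- setNames(config$targets$target, config$targets$outcome)
  for (it in seq_len(iters)) {
    est <- matrix(0, n_reps, length(outs), dimnames = list(NULL, outs))
    est_iq <- matrix(0, n_reps, length(iq_outs),
                     dimnames = list(NULL, iq_outs))
    for (r in seq_len(n_reps)) {
      coh <- generate_cohort(config,
                             seed = (internal_seed + 7919 * it + r) %%
                               2147483646L)
      rep_ <- analyze_cohort(coh)$report
      rd <- rep_[rep_$predictor == "reading_composite", ]
      est[r, ] <- rd$estimate[match(outs, rd$outcome)]
      iqr <- rep_[rep_$predictor == "nonverbal_iq", ]
      est_iq[r, ] <- iqr$estimate[match(iq_outs, iqr$outcome)]
    }
    obs <- colMeans(est)
    obs_iq <- colMeans(est_iq)
    a <- config$reading_paths + (tg[outs] - obs) / rho_c
    b <- config$iq_paths
    b[iq_outs] <- b[iq_outs] + (config$iq_targets - obs_iq)
    # keep the implied covariance positive definite
    scl <- pmin(1, sqrt(0.95 / pmax(a^2 + b^2, 1e-12)))
    config$reading_paths <- a * scl
    config$iq_paths <- b * scl
  }
  config$calibrated <- TRUE
  config
}

#' Paper-calibrated default cohort configuration
#'
#' The study conditions: 38 participants (6 men, 32 women), three
#' reading tests whose pairwise correlations fall in 0.55-0.78 with a
#' dominant first principal component, and visual outcomes whose gated
#' semipartial correlations with the composite reading score (and, for
#' the asymptotes, with nonverbal IQ) match the reported values in
#' expectation. The calibration (see [calibrate_cohort_paths()]) runs
#' once per session and is cached.
#'
#' @param calibrate run the numeric attenuation calibration (`FALSE`
#'   returns the analytic approximation, useful for quick checks).
#' @return a `cohort_config`.
#' @export
default_calibrated_config <- function(calibrate = TRUE) {
  base <- cohort_config()
  paths <- .analytic_paths(base)
  base$reading_paths <- paths$reading
  base$iq_paths <- paths$iq
  if (!calibrate) return(base)
  if (is.null(.tempseg_env$default_config)) {
    .tempseg_env$default_config <- calibrate_cohort_paths(base)
  }
  .tempseg_env$default_config
}

# apply a marginal descriptor to a standard-normal latent column
.apply_marginal <- function(z, m) {
  switch(m$dist,
         lnorm = exp(m$meanlog + m$sdlog * z),
         norm = pmin(pmax(m$mean + m$sd * z, m$lo), m$hi),
         stop("unknown marginal distribution: ", m$dist))
}

#' Generate one synthetic cohort
#'
#' Draws latent reading and nonverbal abilities, builds the three
#' reading raw scores (integer word counts on their test scales), the
#' observed IQ, gender (a fixed number of men at random positions), age,
#' and the eight visual outcomes with the configured cross-correlations
#' and marginals. Fully reproducible from the seed.
#'
#' @param config a [cohort_config()].
#' @param seed integer seed.
#' @return data frame with one row per participant.
#' @export
generate_cohort <- function(config, seed = 1L) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n
  with_seed(seed, {
    lat_read <- rnorm(n)
    lat_iq <- rnorm(n)
    gender <- integer(n)
    gender[sample.int(n, config$n_male)] <- 1L

    lam <- config$reading_loadings
    zs <- vapply(seq_len(3), function(j) {
      lam[j] * lat_read + sqrt(1 - lam[j]^2) * rnorm(n)
    }, numeric(n))
    raw <- vapply(seq_len(3), function(j) {
      sc <- config$reading_scales[[j]]
      pmin(pmax(round(sc["mean"] + sc["sd"] * zs[, j]), sc["lo"]),
           sc["hi"])
    }, numeric(n))

    iq <- round(config$iq_mean + config$iq_sd * lat_iq)
    age <- rnorm(n, config$age_mean, config$age_sd)

    out <- data.frame(participant_id = sprintf("P%02d", seq_len(n)),
                      gender = gender, age_years = age,
                      nonverbal_iq = iq,
                      nart_raw = raw[, 1], towre_swe_raw = raw[, 2],
                      towre_pde_raw = raw[, 3])
    for (oc in .cohort_outcomes()) {
      a <- config$reading_paths[[oc]]
      b <- config$iq_paths[[oc]]
      zlat <- a * lat_read + b * lat_iq +
        sqrt(max(1 - a^2 - b^2, 0)) * rnorm(n)
      out[[oc]] <- .apply_marginal(zlat, config$marginals[[oc]])
    }
  })
  out
}

#' Synthesize a threshold-versus-duration curve
#'
#' Inverts the two-limbed model: thresholds on the duration grid are
#' `two_limbed(x; k, t, s)` perturbed by multiplicative log-normal noise
#' and capped at 100% coherence.
#'
#' @param k,t,s two-limbed parameters (`k` should lie within the grid
#'   support for identifiability; `t` in (0, 100]).
#' @param grid segment durations, seconds.
#' @param noise_sigma sd of the natural-log multiplicative noise (0 for
#'   exact curves).
#' @param seed integer seed.
#' @return data frame with `duration_s` and `threshold_pct`.
#' @export
generate_threshold_curve <- function(k, t, s, grid, noise_sigma = 0.05,
                                     seed = 1L) {
  if (t <= 0 || t > 100) stop("`t` must be in (0, 100]", call. = FALSE)
  if (k <= 0 || s < 0) stop("invalid curve parameters", call. = FALSE)
  y <- two_limbed(grid, k, t, s)
  if (noise_sigma > 0) {
    y <- with_seed(seed, y * exp(rnorm(length(grid), 0, noise_sigma)))
  }
  data.frame(duration_s = grid, threshold_pct = pmin(y, 100))
}

#' Threshold curves for every participant and task
#'
#' @param cohort a [generate_cohort()] table.
#' @param config the generating [cohort_config()] (grid and noise).
#' @param seed integer seed.
#' @return long data frame: `participant_id`, `task`, `duration_s`,
#'   `threshold_pct`.
#' @export
cohort_threshold_curves <- function(cohort, config, seed = 1L) {
  rows <- list()
  for (i in seq_len(nrow(cohort))) {
    for (task in c("motion", "form")) {
      cv <- generate_threshold_curve(
        k = cohort[[paste0(task, "_knee_s")]][i],
        t = min(cohort[[paste0(task, "_asymptote_pct")]][i], 100),
        s = cohort[[paste0(task, "_slope")]][i],
        grid = config$grid, noise_sigma = config$noise_sigma,
        seed = stage_seed(seed, paste0("curve_", task, "_", i)))
      rows[[length(rows) + 1]] <- cbind(
        data.frame(participant_id = cohort$participant_id[i],
                   task = task), cv)
    }
  }
  do.call(rbind, rows)
}

#' Serialize a configuration object to JSON
#'
#' Round-trips [cohort_config()] (and other simple spec objects)
#' losslessly through a JSON file.
#'
#' @param config object to serialize.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_config_json <- function(config, path) {
  # named atomic vectors must become JSON objects, not bare arrays, so
  # their names survive the round trip
  jsonify <- function(x) {
    if (is.data.frame(x)) return(x)
    if (is.list(x)) return(lapply(x, jsonify))
    if (is.atomic(x) && !is.null(names(x))) return(as.list(x))
    x
  }
  payload <- list(class = class(config)[1],
                  fields = jsonify(unclass(config)))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a configuration object written by [write_config_json()]
#'
#' @param path file path.
#' @return the restored object.
#' @export
read_config_json <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  fields <- payload$fields
  if (payload$class == "cohort_config") {
    for (f in c("reading_loadings", "reading_paths", "iq_paths",
                "iq_targets")) {
      fields[[f]] <- unlist(fields[[f]])
    }
    fields$marginals <- lapply(fields$marginals, as.list)
    fields$reading_scales <- lapply(fields$reading_scales, unlist)
  }
  structure(fields, class = payload$class)
}
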