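# stimulus level at which a 2IFC Weibull observer performs at the
# 3-down 1-up convergence point, as a fraction of alpha
.level79_factor <- function(beta, n_down = 3) {
  p <- convergence_probe(n_down)
  (-log(2 * (1 - p)))^(1 / beta)
}

#' Run the end-to-end virtual experiment
#'
#' Composes the full pipeline: synthetic cohort generation, optional
#' staircase measurement of acuities and coherence thresholds, two-limbed
#' curve fitting per participant and task, and the cohort correlation
#' analysis. Every stage draws from a seed derived deterministically from
#' the master seed and the stage name, so a manifest (config + master
#' seed) fully determines every artifact.
#'
#' By default (fast path) participant thresholds are synthesized directly
#' from each participant's two-limbed parameters and acuities are taken
#' as measured. With `simulate_staircases = TRUE` both are instead
#' estimated by running 3-down 1-up staircase sessions against Weibull
#' observers whose thresholds are set from the participant's latent
#' parameters (slow path).
#'
#' @param config a [cohort_config()]; defaults to the calibrated
#'   configuration.
#' @param seed master seed.
#' @param out_dir optional output directory; when given, writes
#'   `cohort.csv`, `curves.csv`, `fits.csv`, `report.csv`,
#'   `report.json` and `manifest.json`.
#' @param simulate_staircases run full staircase sessions instead of the
#'   fast path.
#' @param n_staircases staircases per session (slow path).
#' @param observer_beta psychometric slope of the simulated observers
#'   (slow path).
#' @return list with `cohort`, `curves`, `fits`, `analysis_table`,
#'   `analysis` (report + PCA) and `manifest`.
#' @export
run_end_to_end <- function(config = default_calibrated_config(), seed = 1L,
                           out_dir = NULL, simulate_staircases = FALSE,
                           n_staircases = 4L, observer_beta = 3) {
  stopifnot(inherits(config, "cohort_config"))
  t0 <- Sys.time()
  cohort <- generate_cohort(config, seed = stage_seed(seed, "cohort"))

  if (simulate_staircases) {
    f79 <- .level79_factor(observer_beta)
    acu_cfg <- acuity_staircase_config()
    coh_cfg <- coherence_staircase_config()
    curves <- list()
    for (i in seq_len(nrow(cohort))) {
      for (task in c("motion", "form")) {
        # acuity: staircase on segment duration at 100% coherence
        obs <- observer_spec(
          alpha = cohort[[paste0(task, "_acuity_s")]][i] / f79,
          beta = observer_beta)
        ses <- run_session(acu_cfg, obs, n_staircases,
                           seed = stage_seed(seed,
                                             paste0("acuity_", task, i)))
        cohort[[paste0(task, "_acuity_s")]][i] <- ses$estimate
        # coherence thresholds per grid duration
        k <- cohort[[paste0(task, "_knee_s")]][i]
        tt <- min(cohort[[paste0(task, "_asymptote_pct")]][i], 100)
        ss <- cohort[[paste0(task, "_slope")]][i]
        th <- vapply(seq_along(config$grid), function(g) {
          true_pct <- min(two_limbed(config$grid[g], k, tt, ss), 100)
          obs_g <- observer_spec(alpha = true_pct / 100 * 256 / f79,
                                 beta = observer_beta)
          sg <- run_session(coh_cfg, obs_g, n_staircases,
                            seed = stage_seed(seed,
                                              paste0("coh_", task, i,
                                                     "_", g)))
          max(sg$estimate / 256 * 100, 0.1)
        }, numeric(1))
        curves[[length(curves) + 1]] <- data.frame(
          participant_id = cohort$participant_id[i], task = task,
          duration_s = config$grid, threshold_pct = pmin(th, 100))
      }
    }
    curves <- do.call(rbind, curves)
  } else {
    curves <- cohort_threshold_curves(cohort, config,
                                      seed = stage_seed(seed, "curves"))
  }

  fits <- fit_cohort_curves(curves)

  analysis_table <- cohort
  for (task in c("motion", "form")) {
    sel <- fits$task == task
    idx <- match(cohort$participant_id, fits$participant_id[sel])
    analysis_table[[paste0(task, "_knee_s")]] <- fits$k[sel][idx]
    analysis_table[[paste0(task, "_asymptote_pct")]] <- fits$t[sel][idx]
    analysis_table[[paste0(task, "_slope")]] <- fits$s[sel][idx]
  }
  analysis <- analyze_cohort(analysis_table)

  manifest <- list(
    master_seed = seed,
    stage_seeds = list(cohort = stage_seed(seed, "cohort"),
                       curves = stage_seed(seed, "curves")),
    n = config$n, simulate_staircases = simulate_staircases,
    grid = config$grid, noise_sigma = config$noise_sigma,
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")))

  bundle <- list(cohort = cohort, curves = curves, fits = fits,
                 analysis_table = analysis_table, analysis = analysis,
                 manifest = manifest)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(cohort, file.path(out_dir, "cohort.csv"), row.names = FALSE)
    write.csv(curves, file.path(out_dir, "curves.csv"), row.names = FALSE)
    write.csv(fits, file.path(out_dir, "fits.csv"), row.names = FALSE)
    write.csv(analysis$report, file.path(out_dir, "report.csv"),
              row.names = FALSE)
    jsonlite::write_json(
      list(report = analysis$report,
           pca = list(loadings = analysis$pca$loadings,
                      eigenvalues = analysis$pca$eigenvalues,
                      pct_variance_pc1 = analysis$pca$pct_variance_pc1)),
      file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA,
      pretty = TRUE)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  bundle
}

#' Fit two-limbed curves for every participant and task
#'
#' @param curves long data frame (`participant_id`, `task`,
#'   `duration_s`, `threshold_pct`), as produced by
#'   [cohort_threshold_curves()].
#' @return data frame with one row per participant x task: `k`, `t`,
#'   `s`, `r_squared`, `converged`.
#' @export
fit_cohort_curves <- function(curves) {
  stopifnot(all(c("participant_id", "task", "duration_s",
                  "threshold_pct") %in% names(curves)))
  keys <- unique(curves[c("participant_id", "task")])
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    sub <- curves[curves$participant_id == keys$participant_id[i] &
                    curves$task == keys$task[i], ]
    sub <- sub[order(sub$duration_s), ]
    ft <- fit_two_limbed(sub$duration_s, sub$threshold_pct)
    data.frame(participant_id = keys$participant_id[i],
               task = keys$task[i], k = ft$k, t = ft$t, s = ft$s,
               r_squared = ft$r_squared, converged = ft$converged)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
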