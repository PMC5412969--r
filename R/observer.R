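#' Parametric 2IFC observer
#'
#' A synthetic observer for two-interval forced-choice tasks, used to
#' exercise and validate the adaptive staircases. Performance follows a
#' Weibull psychometric function with guess rate 0.5 (2IFC chance) and an
#' optional lapse rate. `easier_direction = "increasing"` means larger
#' values of the staircase variable make the task easier, which holds for
#' both variables used here: stimulus coherence and segment duration
#' (longer segments are easier to segment).
#'
#' @param alpha threshold location, in the staircase variable's units
#'   (percent coherence / signal elements, or seconds).
#' @param beta psychometric slope (dimensionless, > 0).
#' @param lapse lapse probability in \[0, 0.06\].
#' @param easier_direction `"increasing"` or `"decreasing"`.
#' @return an object of class `observer_spec`.
#' @export
observer_spec <- function(alpha, beta = 3, lapse = 0,
                          easier_direction = c("increasing", "decreasing")) {
  easier_direction <- match.arg(easier_direction)
  stop_if_not_scalar_number(alpha, "alpha", lower = 1e-12)
  stop_if_not_scalar_number(beta, "beta", lower = 1e-12)
  stop_if_not_scalar_number(lapse, "lapse", lower = 0, upper = 0.06)
  structure(list(alpha = alpha, beta = beta, lapse = lapse, guess = 0.5,
                 easier_direction = easier_direction),
            class = "observer_spec")
}

#' Probability of a correct 2IFC response
#'
#' Weibull psychometric function
#' `guess + (1 - guess - lapse) * (1 - exp(-(level/alpha)^beta))` for an
#' observer whose task gets easier as the level increases; monotone
#' non-decreasing in `level`, bounded in `[guess, 1 - lapse]`.
#'
#' @param obs an [observer_spec()].
#' @param level stimulus level(s), >= 0.
#' @return vector of probabilities.
#' @export
p_correct <- function(obs, level) {
  stopifnot(inherits(obs, "observer_spec"))
  if (any(level < 0)) stop("`level` must be non-negative", call. = FALSE)
  x <- if (obs$easier_direction == "increasing") {
    (level / obs$alpha)^obs$beta
  } else {
    ifelse(level == 0, Inf, (obs$alpha / level)^obs$beta)
  }
  obs$guess + (1 - obs$guess - obs$lapse) * (1 - exp(-x))
}

#' Simulate one 2IFC trial
#'
#' Bernoulli draw from [p_correct()], consuming the current RNG stream
#' (seed management is the caller's responsibility, e.g. via
#' [run_staircase()]).
#'
#' @inheritParams p_correct
#' @return logical: response correct?
#' @export
simulate_trial <- function(obs, level) {
  runif(1) < p_correct(obs, level)
}
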