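#' Staircase configuration
#'
#' Parameters of the 3-down 1-up adaptive procedure. After three
#' consecutive correct responses the tracked variable moves "down"
#' (harder: value decreases, since smaller coherence or shorter segments
#' are harder); after any error it moves "up" (easier). The step size
#' halves after every reversal, the run terminates after
#' `total_reversals` reversals, and the threshold is the arithmetic mean
#' of the last `reversals_averaged` reversal values.
#'
#' @param variable `"segment_duration_s"` (temporal-acuity runs) or
#'   `"coherence_elements"` (coherence runs, tracked in signal-element
#'   units).
#' @param initial_value starting value of the variable.
#' @param initial_step starting step size (acuity default 0.215 s;
#'   coherence default the total number of display elements).
#' @param n_down consecutive correct responses required to move down.
#' @param n_up errors required to move up (only 1 is supported).
#' @param total_reversals reversals before termination.
#' @param reversals_averaged trailing reversals averaged into the
#'   threshold.
#' @param lower_bound,upper_bound hard limits; values are clipped (a clip
#'   is not a reversal).
#' @param min_staircases minimum staircases per reported estimate.
#' @param trial_cap safety cap on trials per run.
#' @return an object of class `staircase_config`.
#' @export
staircase_config <- function(variable = c("segment_duration_s",
                                          "coherence_elements"),
                             initial_value, initial_step,
                             n_down = 3L, n_up = 1L,
                             total_reversals = 12L, reversals_averaged = 6L,
                             lower_bound, upper_bound,
                             min_staircases = 4L, trial_cap = 10000L) {
  variable <- match.arg(variable)
  stopifnot(n_down >= 1, n_up == 1,
            reversals_averaged <= total_reversals,
            lower_bound < upper_bound,
            initial_value >= lower_bound, initial_value <= upper_bound,
            initial_step > 0, trial_cap >= 1)
  structure(list(variable = variable, initial_value = initial_value,
                 initial_step = initial_step, n_down = as.integer(n_down),
                 n_up = as.integer(n_up),
                 total_reversals = as.integer(total_reversals),
                 reversals_averaged = as.integer(reversals_averaged),
                 lower_bound = lower_bound, upper_bound = upper_bound,
                 min_staircases = as.integer(min_staircases),
                 trial_cap = as.integer(trial_cap)),
            class = "staircase_config")
}

#' Acuity-run staircase defaults
#'
#' Temporal-acuity runs track segment duration with an initial step of
#' 0.215 s. The staircase starts at the top of the duration range
#' (0.215 s); the lower bound is one frame period and the upper bound the
#' whole stimulus duration.
#'
#' @param frame_rate display rate, Hz.
#' @param n_frames stimulus frames.
#' @return a [staircase_config()].
#' @export
acuity_staircase_config <- function(frame_rate = 100, n_frames = 43L) {
  staircase_config("segment_duration_s",
                   initial_value = 0.215, initial_step = 0.215,
                   lower_bound = 1 / frame_rate,
                   upper_bound = n_frames / frame_rate)
}

#' Coherence-run staircase defaults
#'
#' Coherence runs track the number of signal elements; the initial step
#' equals the total number of elements in the display. Values are kept as
#' reals internally (halved steps quickly produce fractions) and rounded
#' only when a stimulus is constructed.
#'
#' @param n_elements total display elements.
#' @return a [staircase_config()].
#' @export
coherence_staircase_config <- function(n_elements = 256L) {
  staircase_config("coherence_elements",
                   initial_value = n_elements, initial_step = n_elements,
                   lower_bound = 0, upper_bound = n_elements)
}

#' Initial staircase state
#'
#' @param config a [staircase_config()].
#' @return an object of class `staircase_state`.
#' @export
staircase_init <- function(config) {
  stopifnot(inherits(config, "staircase_config"))
  structure(list(config = config,
                 current_value = config$initial_value,
                 current_step = config$initial_step,
                 consecutive_correct = 0L,
                 last_move = "none",
                 reversal_values = numeric(0),
                 trial_values = numeric(0),
                 trial_correct = logical(0),
                 trial_reversal = logical(0),
                 terminated = FALSE),
            class = "staircase_state")
}

#' One 3-down 1-up staircase update
#'
#' Applies a single trial outcome. Three consecutive correct responses
#' move the value down by the current step (and reset the counter); any
#' error moves it up. A reversal is logged when the move direction
#' changes from the previous move; the logged value is the level at which
#' the direction reversed, and the step halves immediately (the reversing
#' move itself uses the halved step). Values are clipped to the
#' configured bounds without logging a reversal.
#'
#' @param state a `staircase_state`.
#' @param correct logical trial outcome.
#' @return the updated `staircase_state`.
#' @export
staircase_update <- function(state, correct) {
  stopifnot(inherits(state, "staircase_state"), is.logical(correct),
            length(correct) == 1, !is.na(correct))
  if (state$terminated) {
    stop("staircase already terminated", call. = FALSE)
  }
  cfg <- state$config
  presented <- state$current_value
  move <- "none"
  if (correct) {
    state$consecutive_correct <- state$consecutive_correct + 1L
    if (state$consecutive_correct >= cfg$n_down) move <- "down"
  } else {
    move <- "up"
  }
  reversal <- FALSE
  if (move != "none") {
    if (state$last_move != "none" && move != state$last_move) {
      reversal <- TRUE
      state$reversal_values <- c(state$reversal_values, presented)
      state$current_step <- state$current_step / 2
    }
    delta <- if (move == "down") -state$current_step else state$current_step
    state$current_value <- min(max(presented + delta,
                                   cfg$lower_bound), cfg$upper_bound)
    state$last_move <- move
    state$consecutive_correct <- 0L
  }
  state$trial_values <- c(state$trial_values, presented)
  state$trial_correct <- c(state$trial_correct, correct)
  state$trial_reversal <- c(state$trial_reversal, reversal)
  if (length(state$reversal_values) >= cfg$total_reversals) {
    state$terminated <- TRUE
  }
  state
}

#' Run one staircase against an observer
#'
#' Loops [simulate_trial()] and [staircase_update()] until the configured
#' number of reversals (or the trial cap). The threshold is the
#' arithmetic mean of the last `reversals_averaged` reversal values.
#'
#' @param config a [staircase_config()].
#' @param observer an [observer_spec()], or a function
#'   `function(level) -> logical` for deterministic/custom responders.
#' @param seed integer seed; fixed seed gives an identical trial log.
#' @return an object of class `staircase_result`: `threshold`,
#'   `n_trials`, `reversal_values`, `converged`, and a `trace` data frame
#'   (trial, value, correct, step, reversal).
#' @export
run_staircase <- function(config, observer, seed = 1L) {
  stopifnot(inherits(config, "staircase_config"))
  respond <- if (is.function(observer)) {
    observer
  } else {
    stopifnot(inherits(observer, "observer_spec"))
    function(level) simulate_trial(observer, level)
  }
  with_seed(seed, {
    state <- staircase_init(config)
    value <- numeric(0); corr <- logical(0)
    stepv <- numeric(0); revf <- logical(0)
    while (!state$terminated && length(value) < config$trial_cap) {
      lev <- state$current_value
      stp <- state$current_step
      ok <- isTRUE(respond(lev))
      n_rev_before <- length(state$reversal_values)
      state <- staircase_update(state, ok)
      value <- c(value, lev); corr <- c(corr, ok); stepv <- c(stepv, stp)
      revf <- c(revf, length(state$reversal_values) > n_rev_before)
    }
  })
  converged <- state$terminated
  rv <- state$reversal_values
  threshold <- if (converged) {
    mean(tail(rv, config$reversals_averaged))
  } else NA_real_
  structure(list(threshold = threshold, n_trials = length(value),
                 reversal_values = rv, converged = converged,
                 trace = data.frame(trial = seq_along(value), value = value,
                                    correct = corr, step = stepv,
                                    reversal = revf)),
            class = "staircase_result")
}

#' Threshold estimate from a session of staircases
#'
#' The reported threshold for an observer is the mean of at least four
#' staircase thresholds.
#'
#' @inheritParams run_staircase
#' @param n_staircases number of staircases (>= `config$min_staircases`).
#' @return list with `estimate`, `per_staircase` thresholds, `sd`,
#'   `converged` (all runs converged) and the individual
#'   `staircase_result`s.
#' @export
run_session <- function(config, observer, n_staircases = 4L, seed = 1L) {
  stopifnot(inherits(config, "staircase_config"))
  if (n_staircases < config$min_staircases) {
    stop(sprintf("at least %d staircases are required per estimate",
                 config$min_staircases), call. = FALSE)
  }
  seeds <- with_seed(seed, sample.int(2147483646L, n_staircases))
  runs <- lapply(seeds, function(s) run_staircase(config, observer, s))
  th <- vapply(runs, `[[`, numeric(1), "threshold")
  list(estimate = mean(th), per_staircase = th,
       sd = sd(th), converged = all(vapply(runs, `[[`, logical(1),
                                           "converged")),
       runs = runs)
}

#' Performance level tracked by an n-down 1-up rule
#'
#' A transformed up-down staircase that needs `n_down` consecutive
#' correct responses to step down converges where the probability of a
#' down-move equals that of an up-move: `p^n_down = 1/2`, i.e.
#' `p = (1/2)^(1/n_down)`. For the 3-down 1-up rule this is 0.7937 — the
#' "79% correct" level.
#'
#' @param n_down consecutive-correct criterion (>= 1).
#' @param n_up errors per up-move; only 1 is supported.
#' @return the tracked probability correct.
#' @export
convergence_probe <- function(n_down, n_up = 1L) {
  if (!is.numeric(n_down) || n_down < 1 || n_down != round(n_down)) {
    stop("`n_down` must be a positive integer", call. = FALSE)
  }
  if (n_up != 1) {
    stop("only n-down 1-up rules are supported", call. = FALSE)
  }
  0.5^(1 / n_down)
}
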