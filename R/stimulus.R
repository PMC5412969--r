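#' Stimulus specification
#'
#' Geometric and temporal parameters of a random-dot stimulus. Defaults
#' reproduce the study display: 43 images of 256 dots shown at 100 Hz
#' (0.43 s total), 0.035 deg per positional update (3.5 deg/s), 0.07 deg
#' dots in a 7 x 7 deg window, 22-frame (0.22 s) limited dot lifetime,
#' 0.52 s inter-stimulus interval. Streak-form images are built by
#' superimposing a 4-frame motion micro-sequence.
#'
#' @param n_dots number of dots per image.
#' @param n_frames number of images in the sequence.
#' @param frame_rate presentation rate, Hz.
#' @param dot_step displacement per positional update, degrees.
#' @param dot_diameter dot diameter, degrees.
#' @param window_size side of the square display window, degrees.
#' @param lifetime_frames limited lifetime of a signal dot, frames.
#' @param isi inter-stimulus interval, seconds (metadata only).
#' @param coherence percentage of signal dots, in \[0, 100\].
#' @param segment_duration duration of one temporal segment, seconds.
#' @param domain_kind `"motion"` or `"form"`.
#' @param arrangement `"segmented"` (alternating blocks) or
#'   `"intermingled"` (same per-frame states in randomized order).
#' @param form_superposition_frames frames superimposed into one form
#'   image.
#' @return an object of class `stimulus_spec`.
#' @export
stimulus_spec <- function(n_dots = 256L, n_frames = 43L, frame_rate = 100,
                          dot_step = 0.035, dot_diameter = 0.07,
                          window_size = 7, lifetime_frames = 22L,
                          isi = 0.52, coherence = 100,
                          segment_duration = 0.215,
                          domain_kind = c("motion", "form"),
                          arrangement = c("segmented", "intermingled"),
                          form_superposition_frames = 4L) {
  domain_kind <- match.arg(domain_kind)
  arrangement <- match.arg(arrangement)
  stop_if_not_scalar_number(n_dots, "n_dots", lower = 1)
  stop_if_not_scalar_number(n_frames, "n_frames", lower = 1)
  stop_if_not_scalar_number(frame_rate, "frame_rate", lower = 1e-6)
  stop_if_not_scalar_number(dot_step, "dot_step", lower = 0)
  stop_if_not_scalar_number(dot_diameter, "dot_diameter", lower = 0)
  stop_if_not_scalar_number(window_size, "window_size", lower = 1e-6)
  stop_if_not_scalar_number(coherence, "coherence", lower = 0, upper = 100)
  stop_if_not_scalar_number(lifetime_frames, "lifetime_frames", lower = 1)
  stop_if_not_scalar_number(form_superposition_frames,
                            "form_superposition_frames", lower = 1)
  stop_if_not_scalar_number(segment_duration, "segment_duration",
                            lower = 1 / frame_rate)
  if (lifetime_frames > n_frames) {
    stop("`lifetime_frames` cannot exceed `n_frames`", call. = FALSE)
  }
  structure(list(
    n_dots = as.integer(n_dots), n_frames = as.integer(n_frames),
    frame_rate = frame_rate, dot_step = dot_step,
    dot_diameter = dot_diameter, window_size = window_size,
    lifetime_frames = as.integer(lifetime_frames), isi = isi,
    coherence = coherence, segment_duration = segment_duration,
    domain_kind = domain_kind, arrangement = arrangement,
    form_superposition_frames = as.integer(form_superposition_frames)
  ), class = "stimulus_spec")
}

#' @export
print.stimulus_spec <- function(x, ...) {
  cat(sprintf(
    "<stimulus_spec> %s/%s: %d dots x %d frames @ %g Hz (%.2f s)\n",
    x$domain_kind, x$arrangement, x$n_dots, x$n_frames, x$frame_rate,
    x$n_frames / x$frame_rate))
  cat(sprintf("  coherence %g%%, segment %g s, step %g deg, window %g deg\n",
              x$coherence, x$segment_duration, x$dot_step, x$window_size))
  invisible(x)
}

#' Build the per-frame state schedule of a stimulus
#'
#' Assigns each frame one of two feature states, `"A"` or `"B"` (motion:
#' leftward/rightward; form: vertical/horizontal). For a segmented
#' arrangement the sequence alternates in blocks: the boundary of segment
#' i falls at frame `round(i * segment_duration * frame_rate)` (half-up
#' frame quantization). The intermingled comparison carries exactly the
#' same multiset of per-frame states in a seeded uniform random order, so
#' local feature statistics match while the temporal block structure is
#' destroyed.
#'
#' @param spec a [stimulus_spec()].
#' @param seed integer seed (used only for the intermingled permutation).
#' @return an object of class `segment_schedule` with elements `states`
#'   (character vector of length `n_frames`), `boundaries` (0-based frame
#'   indices at which the state changes) and `arrangement`.
#' @export
make_segment_schedule <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "stimulus_spec"))
  if (spec$segment_duration < 1 / spec$frame_rate) {
    stop("segment_duration shorter than one frame period", call. = FALSE)
  }
  nf <- spec$n_frames
  frames_per_seg <- spec$segment_duration * spec$frame_rate
  n_seg <- ceiling(nf / frames_per_seg) + 1L
  bounds <- floor(seq_len(n_seg) * frames_per_seg + 0.5) # half-up
  bounds <- bounds[bounds < nf]
  # state of 0-based frame j: number of boundaries at or before j
  j <- seq_len(nf) - 1L
  seg_index <- vapply(j, function(f) sum(bounds <= f), integer(1))
  states <- ifelse(seg_index %% 2 == 0, "A", "B")
  if (spec$arrangement == "intermingled") {
    states <- with_seed(seed, sample(states, length(states)))
  }
  boundaries <- which(diff(match(states, c("A", "B"))) != 0) # 0-based index
  structure(list(states = states, boundaries = boundaries,
                 arrangement = spec$arrangement,
                 segment_duration = spec$segment_duration,
                 frame_rate = spec$frame_rate),
            class = "segment_schedule")
}

#' @export
print.segment_schedule <- function(x, ...) {
  cat(sprintf("<segment_schedule> %s, %d frames, %d state changes\n",
              x$arrangement, length(x$states), length(x$boundaries)))
  cat(" ", paste(x$states, collapse = ""), "\n")
  invisible(x)
}

# signal direction unit vector for a schedule state
.state_direction <- function(state, domain_kind) {
  if (domain_kind == "motion") {
    # A = leftward, B = rightward
    if (state == "A") c(-1, 0) else c(1, 0)
  } else {
    # A = vertical streaks, B = horizontal streaks
    if (state == "A") c(0, 1) else c(1, 0)
  }
}

#' Generate a random-dot motion stimulus
#'
#' Simulates the dot field frame by frame. Signal dots (a
#' `round(coherence/100 * n_dots)` subset, identity fixed for the trial)
#' step `dot_step` degrees in the schedule's current direction on each
#' update; noise dots step the same distance in an independent uniformly
#' random direction (random-walk noise). Positions wrap toroidally inside
#' the square window. Each signal dot carries an age initialized uniformly
#' in 1..lifetime and is replotted at a uniform random location (age reset
#' to 1) once the age exceeds the lifetime.
#'
#' @param spec a [stimulus_spec()] with `domain_kind = "motion"`.
#' @param schedule a [make_segment_schedule()] result.
#' @param seed integer seed; the same seed reproduces the stimulus
#'   bit for bit.
#' @return object of class `dot_stimulus`: a list with `spec`, `schedule`
#'   and `frames`, each frame holding `positions` (n_dots x 2, degrees),
#'   `is_signal`, `age` and `state`.
#' @export
generate_motion_stimulus <- function(spec, schedule, seed = 1L) {
  stopifnot(inherits(spec, "stimulus_spec"),
            inherits(schedule, "segment_schedule"))
  if (spec$domain_kind != "motion") {
    stop("spec$domain_kind must be \"motion\"", call. = FALSE)
  }
  n <- spec$n_dots
  w <- spec$window_size
  n_sig <- as.integer(round_half_up(spec$coherence / 100 * n))
  is_signal <- seq_len(n) <= n_sig
  with_seed(seed, {
    pos <- cbind(runif(n, 0, w), runif(n, 0, w))
    age <- rep(NA_integer_, n)
    age[is_signal] <- sample.int(spec$lifetime_frames, n_sig, replace = TRUE)
    frames <- vector("list", spec$n_frames)
    frames[[1]] <- list(positions = pos, is_signal = is_signal, age = age,
                        state = schedule$states[1])
    for (f in seq_len(spec$n_frames)[-1]) {
      state <- schedule$states[f]
      dir <- .state_direction(state, "motion")
      # noise dots: fresh uniform heading, same step length
      n_noise <- n - n_sig
      if (n_noise > 0) {
        th <- runif(n_noise, 0, 2 * pi)
        pos[!is_signal, 1] <- pos[!is_signal, 1] + spec$dot_step * cos(th)
        pos[!is_signal, 2] <- pos[!is_signal, 2] + spec$dot_step * sin(th)
      }
      if (n_sig > 0) {
        age[is_signal] <- age[is_signal] + 1L
        expired <- is_signal & age > spec$lifetime_frames
        stepping <- is_signal & !expired
        pos[stepping, 1] <- pos[stepping, 1] + spec$dot_step * dir[1]
        pos[stepping, 2] <- pos[stepping, 2] + spec$dot_step * dir[2]
        n_exp <- sum(expired)
        if (n_exp > 0) {
          pos[expired, ] <- cbind(runif(n_exp, 0, w), runif(n_exp, 0, w))
          age[expired] <- 1L
        }
      }
      pos <- pos %% w
      frames[[f]] <- list(positions = pos, is_signal = is_signal,
                          age = age, state = state)
    }
  })
  structure(list(spec = spec, schedule = schedule, frames = frames),
            class = "dot_stimulus")
}

#' Length of a form-task dot streak
#'
#' A streak image superimposes a short motion micro-sequence, so a signal
#' element's extent along its axis is the dot diameter plus
#' `(form_superposition_frames - 1)` positional updates. With the default
#' parameters (0.07 deg dots, 0.035 deg updates, 4 frames) this is
#' 0.175 deg, displayed as 0.18 deg after half-up rounding.
#'
#' @param spec a [stimulus_spec()].
#' @return streak length in degrees (exact value; round with
#'   [round_half_up()] for display).
#' @export
streak_length <- function(spec) {
  stopifnot(inherits(spec, "stimulus_spec"))
  spec$dot_diameter + (spec$form_superposition_frames - 1) * spec$dot_step
}

#' Generate a streak-form stimulus
#'
#' Each displayed frame is a static image built by superimposing a
#' `form_superposition_frames`-frame motion micro-sequence: signal dots
#' translate along the scheduled axis (state A = vertical, B =
#' horizontal), forming oriented streaks, while noise dots take
#' independent random-direction steps and form random clusters. A fresh
#' random image is generated at every frame for both arrangements so that
#' test and comparison stimuli share their update statistics.
#'
#' @inheritParams generate_motion_stimulus
#' @param spec a [stimulus_spec()] with `domain_kind = "form"`.
#' @return object of class `form_stimulus`; each frame holds
#'   `streak_centers` (n_dots x 2, degrees), `is_signal`, `orientation`
#'   (`"vertical"`/`"horizontal"`, signal elements), `dots` (an
#'   n_dots x K x 2 array of the superimposed micro-frame positions) and
#'   `state`.
#' @export
generate_form_stimulus <- function(spec, schedule, seed = 1L) {
  stopifnot(inherits(spec, "stimulus_spec"),
            inherits(schedule, "segment_schedule"))
  if (spec$domain_kind != "form") {
    stop("spec$domain_kind must be \"form\"", call. = FALSE)
  }
  n <- spec$n_dots
  w <- spec$window_size
  k <- spec$form_superposition_frames
  n_sig <- as.integer(round_half_up(spec$coherence / 100 * n))
  is_signal <- seq_len(n) <= n_sig
  sl <- streak_length(spec)
  with_seed(seed, {
    frames <- vector("list", spec$n_frames)
    for (f in seq_len(spec$n_frames)) {
      state <- schedule$states[f]
      dir <- .state_direction(state, "form")
      dots <- array(NA_real_, dim = c(n, k, 2))
      dots[, 1, 1] <- runif(n, 0, w)
      dots[, 1, 2] <- runif(n, 0, w)
      for (m in seq_len(k)[-1]) {
        # micro-steps are tiny relative to the window: no wrap inside the
        # micro-sequence, so each element stays a contiguous streak/cluster
        th <- runif(n, 0, 2 * pi)
        dx <- ifelse(is_signal, spec$dot_step * dir[1],
                     spec$dot_step * cos(th))
        dy <- ifelse(is_signal, spec$dot_step * dir[2],
                     spec$dot_step * sin(th))
        dots[, m, 1] <- dots[, m - 1, 1] + dx
        dots[, m, 2] <- dots[, m - 1, 2] + dy
      }
      centers <- cbind(rowMeans(dots[, , 1, drop = FALSE]),
                       rowMeans(dots[, , 2, drop = FALSE])) %% w
      frames[[f]] <- list(
        streak_centers = centers, is_signal = is_signal,
        orientation = if (state == "A") "vertical" else "horizontal",
        streak_length = sl, dots = dots, state = state)
    }
  })
  structure(list(spec = spec, schedule = schedule, frames = frames),
            class = "form_stimulus")
}

# toroidal displacement between consecutive positions
.wrapped_delta <- function(p2, p1, w) {
  (p2 - p1 + w / 2) %% w - w / 2
}

#' Summarize a generated stimulus
#'
#' Reports the realized coherence, total duration, per-state frame counts,
#' the mean per-update displacement of signal dots (motion stimuli;
#' lifetime replots excluded) and the implied dot speed.
#'
#' @param stim a `dot_stimulus` or `form_stimulus`.
#' @return a list with `n_frames`, `duration_s`, `n_signal`,
#'   `realized_coherence_pct`, `state_counts`, `mean_signal_step_deg` and
#'   `speed_deg_per_s`.
#' @export
stimulus_summary <- function(stim) {
  if (!inherits(stim, c("dot_stimulus", "form_stimulus"))) {
    stop("`stim` must be a dot_stimulus or form_stimulus", call. = FALSE)
  }
  frames <- stim$frames
  if (length(frames) == 0) stop("empty stimulus", call. = FALSE)
  spec <- stim$spec
  states <- vapply(frames, `[[`, character(1), "state")
  n_sig <- sum(frames[[1]]$is_signal)
  mean_step <- NA_real_
  if (inherits(stim, "dot_stimulus") && n_sig > 0 && length(frames) > 1) {
    steps <- numeric(0)
    for (f in seq_along(frames)[-1]) {
      fresh <- frames[[f]]$age == 1L          # replotted this update
      keep <- frames[[f]]$is_signal & !fresh
      if (any(keep)) {
        d <- .wrapped_delta(frames[[f]]$positions[keep, , drop = FALSE],
                            frames[[f - 1]]$positions[keep, , drop = FALSE],
                            spec$window_size)
        steps <- c(steps, sqrt(rowSums(d^2)))
      }
    }
    mean_step <- mean(steps)
  }
  list(
    n_frames = length(frames),
    duration_s = length(frames) / spec$frame_rate,
    n_signal = n_sig,
    realized_coherence_pct = 100 * n_sig / spec$n_dots,
    state_counts = table(factor(states, levels = c("A", "B"))),
    mean_signal_step_deg = mean_step,
    speed_deg_per_s = spec$dot_step * spec$frame_rate
  )
}

#' Tidy data frame of dot trajectories
#'
#' @param x a `dot_stimulus`.
#' @param ... unused.
#' @return data frame with columns `frame`, `dot_id`, `x_deg`, `y_deg`,
#'   `is_signal`, `state`.
#' @export
as.data.frame.dot_stimulus <- function(x, ...) {
  n <- x$spec$n_dots
  do.call(rbind, lapply(seq_along(x$frames), function(f) {
    fr <- x$frames[[f]]
    data.frame(frame = f, dot_id = seq_len(n),
               x_deg = fr$positions[, 1], y_deg = fr$positions[, 2],
               is_signal = fr$is_signal, state = fr$state)
  }))
}

#' Tidy data frame of form-image streak elements
#'
#' @param x a `form_stimulus`.
#' @param ... unused.
#' @return data frame with columns `frame`, `element_id`, `x_deg`,
#'   `y_deg`, `is_signal`, `orientation`, `state`.
#' @export
as.data.frame.form_stimulus <- function(x, ...) {
  n <- x$spec$n_dots
  do.call(rbind, lapply(seq_along(x$frames), function(f) {
    fr <- x$frames[[f]]
    data.frame(frame = f, element_id = seq_len(n),
               x_deg = fr$streak_centers[, 1],
               y_deg = fr$streak_centers[, 2],
               is_signal = fr$is_signal,
               orientation = ifelse(fr$is_signal, fr$orientation, NA),
               state = fr$state)
  }))
}
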