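test_that("segmented schedules quantize boundaries half-up and alternate", {
  # one segment spanning the whole stimulus
  s1 <- make_segment_schedule(stimulus_spec(segment_duration = 0.43))
  expect_equal(s1$states, rep("A", 43))
  expect_length(s1$boundaries, 0)

  # half-stimulus segments: boundary at round(21.5) = 22 (half-up)
  s2 <- make_segment_schedule(stimulus_spec(segment_duration = 0.215))
  expect_equal(s2$boundaries, 22)
  expect_equal(s2$states[1:22], rep("A", 22))
  expect_equal(s2$states[23:43], rep("B", 21))

  # one-frame segments alternate every frame
  s3 <- make_segment_schedule(stimulus_spec(segment_duration = 0.01))
  expect_equal(s3$states, rep(c("A", "B"), length.out = 43))

  expect_error(stimulus_spec(segment_duration = 0.005),
               "segment_duration")
})

test_that("segmented run lengths track segment_duration within one frame", {
  for (d in c(0.03, 0.0525, 0.082, 0.1, 0.215)) {
    sch <- make_segment_schedule(stimulus_spec(segment_duration = d))
    runs <- rle(sch$states)$lengths
    # interior runs only: the last may be truncated by the stimulus end
    interior <- head(runs, -1)
    expect_true(all(abs(interior - d * 100) <= 1),
                label = sprintf("run lengths at d = %g", d))
  }
})

test_that("intermingled schedules permute, and preserve, per-state counts", {
  spec_seg <- stimulus_spec(segment_duration = 0.0525)
  spec_int <- stimulus_spec(segment_duration = 0.0525,
                            arrangement = "intermingled")
  seg <- make_segment_schedule(spec_seg)
  int <- make_segment_schedule(spec_int, seed = 9)
  expect_equal(table(int$states), table(seg$states))
  expect_false(identical(int$states, seg$states))
  # deterministic under the seed
  expect_identical(int$states,
                   make_segment_schedule(spec_int, seed = 9)$states)
})

test_that("motion stimulus respects window, coherence count and steps", {
  spec <- stimulus_spec(coherence = 50)
  sch <- make_segment_schedule(spec)
  stim <- generate_motion_stimulus(spec, sch, seed = 21)
  w <- spec$window_size
  for (fr in stim$frames) {
    expect_true(all(fr$positions >= 0 & fr$positions < w))
  }
  expect_equal(sum(stim$frames[[1]]$is_signal), 128)

  # every non-replotted dot (signal or noise) moves exactly dot_step
  for (f in c(2, 10, 30)) {
    fresh <- !is.na(stim$frames[[f]]$age) & stim$frames[[f]]$age == 1L
    d <- wrap_delta(stim$frames[[f]]$positions[!fresh, ],
                    stim$frames[[f - 1]]$positions[!fresh, ], w)
    expect_equal(sqrt(rowSums(d^2)), rep(spec$dot_step, sum(!fresh)),
                 tolerance = 1e-12)
  }

  # signal dots move along the scheduled axis; at full coherence and one
  # segment every update is (-dot_step, 0)
  spec100 <- stimulus_spec(coherence = 100, segment_duration = 0.43)
  st100 <- generate_motion_stimulus(spec100,
                                    make_segment_schedule(spec100), 3)
  for (f in c(2, 20, 43)) {
    keep <- st100$frames[[f]]$age != 1L
    d <- wrap_delta(st100$frames[[f]]$positions[keep, ],
                    st100$frames[[f - 1]]$positions[keep, ], w)
    expect_equal(d[, 1], rep(-spec100$dot_step, sum(keep)),
                 tolerance = 1e-12)
    expect_equal(d[, 2], rep(0, sum(keep)), tolerance = 1e-12)
  }
})

test_that("zero coherence yields no signal dots, random headings", {
  spec <- stimulus_spec(coherence = 0)
  stim <- generate_motion_stimulus(spec, make_segment_schedule(spec), 5)
  expect_equal(sum(stim$frames[[1]]$is_signal), 0)
  d <- wrap_delta(stim$frames[[2]]$positions,
                  stim$frames[[1]]$positions, spec$window_size)
  expect_equal(sqrt(rowSums(d^2)), rep(spec$dot_step, spec$n_dots),
               tolerance = 1e-12)
  # headings are not aligned with any single axis
  expect_gt(sd(atan2(d[, 2], d[, 1])), 0.5)
})

test_that("limited lifetime replots at ~1/lifetime rate to random places", {
  spec <- stimulus_spec(coherence = 100)
  stim <- generate_motion_stimulus(spec, make_segment_schedule(spec), 8)
  ages <- vapply(stim$frames, function(fr) fr$age, integer(spec$n_dots))
  expect_true(all(ages >= 1 & ages <= spec$lifetime_frames))
  replots <- sum(ages[, -1] == 1L)
  n_updates <- (spec$n_frames - 1) * spec$n_dots
  expect_equal(replots / n_updates, 1 / spec$lifetime_frames,
               tolerance = 0.15)
  # replotted dots land at positions uncorrelated with their previous one
  jumps <- numeric(0)
  for (f in 2:spec$n_frames) {
    fresh <- ages[, f] == 1L
    if (any(fresh)) {
      d <- wrap_delta(stim$frames[[f]]$positions[fresh, , drop = FALSE],
                      stim$frames[[f - 1]]$positions[fresh, , drop = FALSE],
                      spec$window_size)
      jumps <- c(jumps, sqrt(rowSums(d^2)))
    }
  }
  expect_gt(mean(jumps), 10 * spec$dot_step)
})

test_that("same seed reproduces a stimulus bit for bit", {
  spec <- stimulus_spec(coherence = 35)
  sch <- make_segment_schedule(spec)
  expect_identical(generate_motion_stimulus(spec, sch, 77),
                   generate_motion_stimulus(spec, sch, 77))
  fspec <- stimulus_spec(domain_kind = "form", coherence = 35,
                         n_dots = 64, n_frames = 10, lifetime_frames = 5)
  fsch <- make_segment_schedule(fspec)
  expect_identical(generate_form_stimulus(fspec, fsch, 77),
                   generate_form_stimulus(fspec, fsch, 77))
})

test_that("streak length follows the superposition formula", {
  expect_equal(streak_length(stimulus_spec()), 0.175)
  expect_equal(round_half_up(streak_length(stimulus_spec()), 2), 0.18)
  expect_equal(streak_length(stimulus_spec(form_superposition_frames = 1)),
               0.07)
  expect_equal(streak_length(stimulus_spec(form_superposition_frames = 2)),
               0.105)
})

test_that("form images hold oriented signal streaks and noise clusters", {
  spec <- stimulus_spec(domain_kind = "form", coherence = 50, n_dots = 80,
                        n_frames = 8, lifetime_frames = 5,
                        segment_duration = 0.04)
  sch <- make_segment_schedule(spec)
  fs <- generate_form_stimulus(spec, sch, seed = 4)
  sl <- streak_length(spec)
  for (f in c(1, 5, 8)) {
    fr <- fs$frames[[f]]
    expect_equal(fr$orientation,
                 if (sch$states[f] == "A") "vertical" else "horizontal")
    sig <- fr$is_signal
    ax <- if (fr$orientation == "vertical") 2 else 1
    perp <- 3 - ax
    span_ax <- apply(fr$dots[sig, , ax], 1, function(v) diff(range(v)))
    span_pp <- apply(fr$dots[sig, , perp], 1, function(v) diff(range(v)))
    # signal elements are collinear streaks of the predicted extent
    expect_equal(span_ax + spec$dot_diameter, rep(sl, sum(sig)),
                 tolerance = 1e-12)
    expect_equal(span_pp, rep(0, sum(sig)), tolerance = 1e-12)
    expect_equal(fr$streak_length, sl)
  }
  # noise elements are scattered clusters, not common-axis streaks
  fr <- fs$frames[[1]]
  nz <- !fr$is_signal
  span_x <- apply(fr$dots[nz, , 1], 1, function(v) diff(range(v)))
  span_y <- apply(fr$dots[nz, , 2], 1, function(v) diff(range(v)))
  expect_gt(mean(pmin(span_x, span_y)), 0)
})

test_that("zero-coherence form images contain only random clusters", {
  spec <- stimulus_spec(domain_kind = "form", coherence = 0, n_dots = 60,
                        n_frames = 6, lifetime_frames = 5,
                        segment_duration = 0.03)
  fs <- generate_form_stimulus(spec, make_segment_schedule(spec), 2)
  fr <- fs$frames[[1]]
  expect_equal(sum(fr$is_signal), 0)
  span_x <- apply(fr$dots[, , 1], 1, function(v) diff(range(v)))
  span_y <- apply(fr$dots[, , 2], 1, function(v) diff(range(v)))
  # a common-axis streak would have zero spread on one axis
  expect_true(all(pmax(span_x, span_y) > 0))
  expect_gt(mean(pmin(span_x, span_y)), 0.005)
})

test_that("stimulus summary reports the canonical display constants", {
  spec <- stimulus_spec(coherence = 50)
  stim <- generate_motion_stimulus(spec, make_segment_schedule(spec), 31)
  s <- stimulus_summary(stim)
  expect_equal(s$duration_s, 0.43)
  expect_equal(s$speed_deg_per_s, 3.5)
  expect_equal(s$n_signal, 128)
  expect_equal(s$mean_signal_step_deg, spec$dot_step, tolerance = 1e-12)
  expect_equal(sum(s$state_counts), 43)
  expect_error(stimulus_summary(list()), "dot_stimulus")
})

test_that("tidy exports carry one row per dot and frame", {
  spec <- stimulus_spec(n_dots = 16, n_frames = 5, lifetime_frames = 4,
                        coherence = 50, segment_duration = 0.02)
  df <- as.data.frame(generate_motion_stimulus(
    spec, make_segment_schedule(spec), 1))
  expect_equal(nrow(df), 16 * 5)
  expect_named(df, c("frame", "dot_id", "x_deg", "y_deg", "is_signal",
                     "state"))
})
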