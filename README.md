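# tempseg

Simulation and analysis toolkit for **temporal-segmentation
psychophysics** — the paradigm in which observers discriminate
random-dot stimuli whose feature state (motion direction, or the
orientation of dot streaks) alternates in time from comparison stimuli
carrying the same cues temporally intermingled. The package targets
researchers in visual psychophysics and reading/dyslexia research who
want a fully verifiable, data-free implementation of the measurement
chain used to relate temporal visual acuity to reading skill.

It implements, as tested R functions:

* **Stimuli** — temporally segmented and intermingled random-dot motion
  sequences (43 × 256 dots at 100 Hz, 0.035°/update, 22-frame limited
  lifetime, 7°×7° window) and streak-form images built by superimposing
  4-frame micro-sequences (streak length 0.07 + 3×0.035 = 0.175°,
  displayed 0.18°).
* **Adaptive staircases** — the 3-down 1-up transformed up-down rule,
  tracking the (1/2)^(1/3) ≈ 79% correct level, with step halving at
  every reversal, termination at 12 reversals, thresholds as the mean
  of the last six, and session estimates over ≥ 4 staircases; driven by
  parametric Weibull 2IFC observers.
* **Two-limbed curve fits** — the broken-stick model
  *y(x) = t·(k/x)^s* for *x < k* and *y(x) = t* for *x ≥ k*, fit by
  profiled-knee least squares with Levenberg–Marquardt polish on
  log₁₀ thresholds; *k* is the knee-point, *t* the asymptotic coherence
  threshold, *s* the descending-limb slope.
* **Cohort statistics** — correlation-matrix PCA composite of three
  reading tests (NART, TOWRE Sight Word Efficiency and Phonemic
  Decoding Efficiency), a Shapiro–Wilk normality gate choosing Pearson
  vs Spearman per outcome, and semipartial correlations of the
  composite with eight visual outcomes controlling gender and
  nonverbal IQ (plus IQ–asymptote semipartials controlling reading and
  gender).
* **A calibrated synthetic cohort** — a Gaussian-copula generator
  (n = 38; 6 men) whose observable, gated semipartial correlations are
  numerically calibrated to match its target effect sizes in
  expectation, so the whole pipeline is testable end to end without
  human data.

## Worked example

```r
library(tempseg)

## a segmented motion stimulus at an 80 ms segment duration
spec <- stimulus_spec(coherence = 100, segment_duration = 0.0803)
stim <- generate_motion_stimulus(spec, make_segment_schedule(spec, seed = 1),
                                 seed = 1)
str(stimulus_summary(stim)[c("duration_s", "n_signal", "speed_deg_per_s")])
#> List of 3
#>  $ duration_s     : num 0.43
#>  $ n_signal       : int 256
#>  $ speed_deg_per_s: num 3.5

## a temporal-acuity session: four 3-down 1-up staircases vs a Weibull
## observer with threshold parameter 0.1 s
obs <- observer_spec(alpha = 0.1, beta = 3)
acu <- run_session(acuity_staircase_config(), obs, n_staircases = 4, seed = 7)
#> acuity estimate: 0.067 s from staircases 0.086, 0.080, 0.015, 0.088

## a synthetic cohort through curve fitting and the correlation pipeline
cfg    <- default_calibrated_config()          # calibrated; cached per session
cohort <- generate_cohort(cfg, seed = 60)
curves <- cohort_threshold_curves(cohort, cfg, seed = 60)
sub <- curves[curves$participant_id == "P01" & curves$task == "motion", ]
fit_two_limbed(sub$duration_s, sub$threshold_pct)
#> <two_limbed_fit> k = 0.07614 s, t = 15.09 %, s = 1.05, R^2 = 0.990

res <- analyze_cohort(cohort)
#> PC1 explains 76% (eigenvalues 2.27/0.46/0.27); loadings 0.84/0.91/0.86
res$report[c(1, 5), c("outcome", "method", "estimate", "p_value")]
#>           outcome   method estimate p_value
#> 1 motion_acuity_s spearman    -0.44 7.6e-03
#> 5   form_acuity_s  pearson    -0.63 4.6e-05
```

The fitted knee (0.076 s) is the segment duration above which this
participant's coherence thresholds stop improving; the asymptote
(15.1% coherence) is their best achievable threshold, and R² = 0.99
says the broken stick describes the synthetic curve well. In the cohort
report, negative composite–acuity correlations mean poorer readers need
longer segments; any single cohort of 38 is noisy (here −0.44 and
−0.63), and the calibrated effect sizes (−0.46 motion, −0.40 form)
emerge as averages over replicate cohorts — see below.

## Analysis workflow

The `analysis/` scripts are thin narrative drivers over the package and
write their tables to `results/`:

1. `01_stimuli.R` — stimulus construction, schedule bookkeeping, tidy
   trajectory/element exports.
2. `02_staircases.R` — convergence probe, deterministic-observer
   oracle, Monte-Carlo tracking study, a session demo.
3. `03_curve_fits.R` — synthesizes curves for a cohort, fits all
   76 participant×task curves, reports fit quality and recovery.
4. `04_cohort_analysis.R` — single-cohort report, 500-replicate
   recovery of the calibrated effect sizes, one full end-to-end run.

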