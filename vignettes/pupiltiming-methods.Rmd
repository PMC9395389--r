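---
title: "Methods: time-estimation behavior and pupillometry with pupiltiming"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: time-estimation behavior and pupillometry with pupiltiming}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## What the package computes

`pupiltiming` analyzes a visually cued time-estimation task: on each trial
the participant presses a key as close as possible to a 1200-ms target
interval after a cue, receives immediate visual feedback of the produced
interval on a scale clamped to 600--1800 ms, and a head-mounted eye tracker
records binocular pupil diameter at 60 Hz. The design of interest is a 2x2
mixed layout -- a between-subject Group factor (e.g. patients vs. controls)
crossed with a within-subject Session factor (e.g. ON vs. OFF medication) --
with 120 trials per session in two blocks and intertrial intervals jittered
between 1700 and 2300 ms.

Three families of quantities are produced per participant and session:

1. **Behavioral summaries** -- mean RT and mean absolute timing error
   |error| = |RT - 1200|, and the *sequential adjustment* regression
   `dRT[t] = b0 + b1*RT[t-1] + b2*RT[t-1]*|error|[t-1]`, where
   `dRT[t] = RT[t] - RT[t-1]`. `b1` absorbs regression to the mean (for an
   uncorrelated RT series it converges to exactly -1, which the test suite
   verifies by closed form); `b2`, the adjustment coefficient, captures
   error-magnitude-driven correction over and above it.
2. **Task-related pupil response** -- the cleaned, normalized pupil signal
   segmented [-1500, 1000] ms around the response, baseline-corrected by the
   mean of the 400 ms preceding the *stimulus*, averaged over kept trials,
   tested against zero per time point across participants.
3. **Feedback-related pupil sensitivity** -- the [0, 1500] ms post-feedback
   segment with a pre-*response* baseline; per time point, the single-trial
   regression `d ~ b0 + b1*|error|` across trials yields a sensitivity time
   course whose group-level peak defines the scalar-extraction windows.

Group inference uses mixed ANOVAs (Group between, Session within) with
partial eta squared, per-cell one-sample t-tests with step-down-adjusted
p-values, rank tests as non-parametric fallbacks, and exploratory Pearson
correlations (including against body-weight-normalized levodopa dose).

## The synthetic cohort generator

No public dataset accompanies this design, so the package ships a forward
simulator ([sim_truth()], [cohort_spec()], [simulate_cohort()]) that is
first-class, tested code: every downstream stage is validated by recovering
known generative parameters.

### Behavior

RT sequences follow the *generative twin* of the analysis regression:

    RT[t] = RT[t-1] + a0 + a1*RT[t-1] + a2*RT[t-1]*|error|[t-1] + eps[t]

with `eps ~ N(0, sigma_motor^2)` and the first trial of each block drawn
from `N(mu_rt, sigma_motor^2)`. Defaults (chosen once, on realism):

| parameter     | default | units | rationale                                   |
|---------------|---------|-------|---------------------------------------------|
| `mu_rt`       | 1200    | ms    | anchored to the target interval             |
| `sigma_motor` | 80      | ms    | ~7% CV, typical motor-timing variability    |
| `a1`          | -0.8    | --    | lag-1 RT autocorrelation ~0.2, the weak positive dependence produced-interval series show |
| `a2`          | -4e-4   | 1/ms  | error-driven correction; in ms units the coefficient is numerically small by construction |
| `a0`          | solved  | ms    | set so `mu_rt` is the fixed point of the dynamics |

Configurations whose linearized dynamics are non-contracting
(|1 + a1 + a2*E|error|| >= 1 with noise) are rejected with a diagnostic.
Responses that would exceed the 2000-ms trial timeout are truncated and
flagged as missing (lapses); the paper-style analysis drops such trials
listwise from pair formation.

### Pupil

The diameter signal is composed additively per sample:

    diam(t) = tonic + drift(t) + task(t) + feedback(t) + noise

* **Impulse response**: the gamma-family kernel
  `K(t) = (t/tmax)^n exp(n(1 - t/tmax))` with `n = 10.1`, `tmax = 0.93` s,
  the standard psychophysiological pupil response, unit-peak normalized.
* **Task drive**: a boxcar from stimulus onset to response, convolved with
  the unit-*area* kernel and scaled by `g_task` (so a long drive saturates
  at exactly `g_task`); evaluated in closed form via the incomplete-gamma
  kernel integral, which is what lets tests assert the noise-free forward
  model exactly at every sample. An impulse-at-stimulus drive can be
  emulated by setting the response time short.
* **Feedback response**: an impulse at the response, amplitude
  `g_fb + g_err * |error|` -- the error-scaled component whose recovery
  through the entire pipeline (cleaning, filtering, normalization,
  epoching, time-resolved regression) is the package's central
  forward-inverse consistency check.
* **Drift**: a stationary Ornstein-Uhlenbeck process (SD 0.08 a.u., time
  constant 20 s) shared between the eyes; **noise**: independent white
  noise per eye (SD 0.03 a.u.).
* **Blinks**: Poisson events (12/min left eye; the right eye gets twice the
  rate so eye selection has a correct answer) with log-normal duration
  (median 150 ms), a 30% diameter drop with 50-ms linear ramps, and
  confidence forced to 0.1 for the whole event. These values are arbitrary
  but fixed; artifact insertion provably never alters samples outside the
  flagged interval.

**What the generator does not emulate**: gaze-angle foreshortening,
luminance responses, saccade- or tremor-related artifacts, slow vigilance
nonstationarities beyond the OU drift, or asymmetric eye physiology. A
passing recovery test therefore demonstrates the *pipeline's* correctness
under the stated generative assumptions, not robustness to every failure
mode of real recordings.

## Preprocessing decisions

* **Eye selection**: the eye with the larger fraction of samples at
  confidence >= 0.6; exact ties break to the left eye.
* **Artifact detection**: confidence < 0.6, or |first difference| > 4 SD of
  first differences. The SD is computed per block, in one pass, over
  differences untouched by confidence-flagged samples. A diagnosed
  consequence worth knowing: in nearly noise-free signals the background
  difference SD is so small that the steepest *genuine* response rises can
  exceed 4 SD and be flagged; with realistic measurement noise the
  criterion behaves as intended. This is a property of the prescribed rule,
  not of its implementation.
* **Interpolation**: linear between nearest clean neighbors; leading and
  trailing runs are filled by nearest-value extension (no extrapolation).
* **Filtering**: 3rd-order Butterworth high-pass at 0.06 Hz then low-pass
  at 6 Hz, each applied forward-backward (zero phase), per block. Zero
  phase is essential because event latencies (peaks near half a second) are
  interpreted; the net magnitude response is the squared single-pass
  response, and tests verify measured sinusoid gains against the analytic
  magnitude on the bilinear-prewarped frequency axis -- the exact closed
  form for a digitally designed Butterworth filter. The implementation
  initializes the filter state at its DC steady state and pads with odd
  reflection (3 s), because zero-state filtering at a 0.06 Hz cutoff would
  otherwise ring for tens of seconds at block edges; a constant input maps
  to exactly zero output. Blocks shorter than 3x the edge-transient span
  are marked unusable rather than filtered badly.
* **Normalization**: 100 * value / median, with the median taken per block
  from the *interpolated, unfiltered* signal (spikes would bias a raw
  median). Normalizing the pre-filter signal by itself yields a per-block
  median of exactly 100 -- an identity the acceptance suite checks
  literally. Because white noise smears a positively skewed signal, the
  median (hence the normalization denominator) sits slightly above the
  tonic level in noisy recordings; the effect is sub-percent at default
  noise levels.
* Filtering and normalization are strictly per block: blocks are separated
  by pauses, and filtering across the gap would smear discontinuities.

## Epoching and rejection

Sample windows are half-open `[start, end)` on the native 60-Hz grid (no
resampling anywhere), and lock times map to the nearest sample at or before
the event -- together this gives unambiguous counts (150 samples for the
task window, 24 for each 400-ms baseline). Rejection applies identically to
both segmentation modes and reads the rules literally: RT < 400 ms;
strictly more than 50% of epoch samples artefactual; any overlap -- even
one sample -- with a single artifact interval strictly longer than 750 ms.
A constructed 120-trial session with 7 designed violations (2 fast RTs, 3
over-50% epochs, 2 long-interval overlaps) must keep exactly 113 trials
with the right reason codes.

## Time-resolved statistics

Per time point, one-sample t-tests across participants (sessions averaged
within participant first) use a pointwise two-sided alpha of 0.05 with *no*
correction across time points; the output reports the maximal contiguous
significant interval. This mirrors the common reporting style for pupil
time courses and is flagged here deliberately: contiguous-interval onsets
are descriptive, not familywise-controlled claims.

Peak handling: the task-related peak is searched over the full
[-1.5, 1.0] s interval; the feedback-related peak is located on the
group-mean `b1(t)` curve in [0, 1.5] s, and *both* the feedback dilation
and the sensitivity scalars are extracted around that regression peak.
Scalars are means in closed windows of +/-250 ms (31 samples) and +/-50 ms
(7 samples). [window_mean()] refuses windows that leave the analysis
interval; when a group peak lands close enough to the interval edge that
the window cannot fit, the pipeline shifts the center inward by the minimal
amount and logs the adjustment rather than silently clipping.

Zero-variance time points leave the t statistic defined (0) only when the
mean is also exactly zero; the p-value is flagged undefined either way.

## Group inference

The mixed ANOVA uses the classical decomposition: subjects-within-groups
error tests Group; the subject-by-session stratum tests Session and the
interaction. Partial eta squared is `SS_effect / (SS_effect + SS_error)`
with each effect's own error term, and a Shapiro-Wilk test on the
within-cell residuals accompanies every table (motivating the rank-based
fallback: the Session-2-minus-Session-1 change compared between groups by
Mann-Whitney). The test suite holds the implementation against an explicit
sums-of-squares oracle on random balanced designs and checks the
interaction test's type-I rate on 400 null cohorts (5% within +/-2 points).

The adjustment-score one-sample tests adjust p across the four
group-by-session cells by Holm step-down -- uniformly more powerful than
Bonferroni and the conventional default when the adjustment method is
otherwise unspecified; the method is a configuration option. Rank tests
enumerate the exact permutation null for n <= 12 per group without ties and
otherwise use the normal approximation with continuity correction.
Correlations (including dose correlations on OFF-minus-ON change scores)
are reported as exploratory and never multiplicity-corrected.

### Parameter-recovery design

Recovery of the behavioral coefficients at the study's own scale (200
subjects x 120 trials) is checked with a *pooled* OLS across subjects
rather than by averaging per-subject fits. The reason is statistical, not
computational: a regression containing the lagged dependent variable has
the classical O(1/T) small-sample bias (about -(1+3*rho)/T on the lag
coefficient), which at T = 118 pairs is the same order as three Monte-Carlo
standard errors of a 200-subject mean -- per-subject averaging would test
the well-known bias of the estimator, not the correctness of the
implementation. The pooled estimator is consistent (bias O(1/(N*T))) and
recovers each of (a0, a1, a2) within 3 standard errors.

### Effect-size calibration

With a programmed patient-session-2 motor-noise multiplier of 1.10 (a
~7 ms shift of mean |error|), simulated cohorts at n = 12/group produce
interaction effects of median partial eta squared 0.189, and the mixed
ANOVA detects the interaction in 58% of 100 replicates (computed by the
test suite at its fixed seed). The default cohort effects shipped with the
generator are deliberately larger (patient session-2: sigma_motor x1.25,
a2 x0.40, g_err x0.60), so that a single simulated cohort at the default
seed shows the qualitative pattern clearly.

## Problem sizes and determinism

Validation uses: 1000 random instances for the OLS oracles; 100,000 pairs
for the regression-to-the-mean closed form; 200 subjects for behavioral
recovery; 6 noise-free plus 12 fully noisy subjects for pupil-gain
recovery (the noisy cohort is sized so the between-subject SE -- dominated
by slow-drift realizations -- is itself estimated stably); 400 null
cohorts for type-I calibration. These sizes make the whole validation run
in a few minutes on one core while keeping every Monte-Carlo band at least
three standard errors wide.

Every stochastic step is seed-controlled. The results bundle (CSV tables,
JSON statistics, QC report, manifest, log) contains no timestamps, and its
manifest carries an MD5 hash of all analysis constants, so identical
(dataset, config, seed) reproduce the bundle byte for byte.

## Known limitations

* The pointwise-alpha time-resolved tests do not control familywise error
  over time; interval onsets should be read descriptively.
* The per-block median normalization makes percent-change values depend on
  block composition; blocks with strong tonic trends shift the denominator.
* The linear-interpolation repair flattens genuine signal under long
  artifacts; the 750-ms overlap rule is the guard, but epochs kept with
  shorter interpolated stretches are mildly amplitude-attenuated.
* A confirmatory mixed-effects analysis controlling for raw pupil diameter
  and mean RT is out of scope here; its random-effects structure is not
  specified by the analysis conventions this package encodes.
* Exact rank-test enumeration is delegated to `stats::wilcox.test`; with
  ties the normal approximation is used even at small n.
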