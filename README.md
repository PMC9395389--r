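# pupiltiming

Analysis pipeline for interval-timing experiments with concurrent
pupillometry, aimed at researchers studying sensorimotor timing, feedback
processing and pupil-linked arousal in clinical 2x2 designs (a
between-subject Group factor crossed with a within-subject Session factor,
e.g. patients measured ON and OFF medication vs. controls).

The task it models: participants press a key as close as possible to a
**1200-ms target** after a visual cue; feedback shows the produced interval
on a scale clamped to **600–1800 ms**; 120 trials per session in two
blocks; binocular pupil diameter recorded at **60 Hz**.

## What it computes

**Sequential adjustment.** Per participant-session, ordinary least squares
on

$$\Delta RT_t = \beta_0 + \beta_1\, RT_{t-1} + \beta_2\, RT_{t-1}\,|error|_{t-1},$$

where $\Delta RT_t = RT_t - RT_{t-1}$ and $|error|_t = |RT_t - 1200|$.
$\beta_1$ absorbs regression to the mean (exactly $-1$ for an uncorrelated
series); $\beta_2 < 0$ — the *adjustment coefficient* — means speeding
after especially slow responses and slowing after fast ones.

**Pupil preprocessing.** Eye selection by fraction of samples at
confidence ≥ 0.6; artifact flagging by the same confidence threshold plus a
4-SD first-derivative criterion; linear interpolation; zero-phase 3rd-order
Butterworth filtering (0.06 Hz high-pass, 6 Hz low-pass); normalization to
percent of the per-block pre-filter median.

**Event-locked analysis.** Task mode: [−1500, 1000] ms around the response
with a [−400, 0] ms pre-*stimulus* baseline; feedback mode: [0, 1500] ms
with a pre-*response* baseline. Trials are rejected when RT < 400 ms, when
>50% of epoch samples are artefactual, or when the epoch overlaps an
artifact interval longer than 750 ms. Time-resolved statistics: one-sample
t-tests of the group-average response against zero per time point, and the
single-trial regression $d \sim \beta_0 + \beta_1 |error|$ of feedback-locked
dilation on performance error; peak-window scalars (±250 ms / ±50 ms) feed
mixed ANOVAs (Group × Session) with partial $\eta_p^2$, Holm-adjusted
one-sample tests, Mann–Whitney/Wilcoxon fallbacks and exploratory Pearson
correlations (including body-weight-normalized levodopa dose).

**Synthetic cohorts.** Because no public dataset accompanies this design,
the package includes a seeded forward simulator — behavior from the
generative twin of the adjustment model, pupil traces composed of a
gamma-family impulse response (peak 0.93 s) driven by a
stimulus-to-response boxcar and an error-scaled feedback impulse, plus
drift, noise and blink-like artifacts with low confidence — with a written
ground-truth ledger, so the whole pipeline is testable by parameter
recovery.

## Worked example

```r
library(pupiltiming)

spec   <- cohort_spec()            # 12+12 x 2 sessions x 120 trials
truth  <- sim_truth(seed = 42)     # generative ground truth
trials <- simulate_behavior(spec, truth, seed = 42)

summarize_behavior(trials)
#>   n_trials n_valid mean_rt mean_abs_error
#> 1      120     120 1199.35       72.07636

fit_adjustment_model(trials)
#> Trial-to-trial adjustment model (OLS on 118 pairs)
#>   b0 (intercept)        995.395 ms  (SE 103.510)
#>   b1 (lag RT)           -0.7955     (SE 0.0861)
#>   b2 (adjustment)    -4.902e-04 /ms (SE 1.26e-04)

samples <- simulate_pupil(trials, truth)
trace   <- preprocess_pupil(samples)
fb      <- reject_trials(extract_epochs(trace, trials, feedback_epoch_spec()),
                         attr(trace, "intervals"))
er      <- timewise_error_regression(fb)
find_peak(list(time = er$time, values = er$beta1), c(0, 1.5))
#> feedback error-sensitivity peak: beta1 = 0.0499 %/ms at 0.950 s
```

The recovered quantities line up with the ground truth: the generative
coefficients were $a_1 = -0.8$, $a_2 = -4\times10^{-4}$, and the feedback
error gain was 0.002 a.u./ms on a tonic diameter of 4 a.u., i.e. a
normalized sensitivity of $100 \times 0.002 / 4 = 0.05$ %/ms peaking at the
kernel latency 0.93 s — the fitted values above are within one standard
error or one sample of each.

A full cohort run (simulate → preprocess → epoch → analyze → report):

```r
cfg <- run_config(input = "cohort", output = "results", simulate = TRUE,
                  seed = 1)
run_pipeline(cfg)
```

writes `behavior_summaries.csv`, `peak_scalars.csv`, `timecourses.csv`,
`qc.csv`, `group_stats.json`, a config-hashed `manifest.json` and a
deterministic `log.txt`. The same pipeline is scriptable from a shell via
`inst/cli/pupiltiming` (`--stage simulate|analyze|all`, `--config`,
`--input`, `--output`, `--seed`, `--overwrite`).

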