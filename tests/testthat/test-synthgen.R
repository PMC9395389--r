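test_that("noise-free dynamics stay pinned to the target fixed point", {
  spec <- cohort_spec(n_per_group = 1, n_trials = 40, n_blocks = 2,
                      effects = NULL)
  truth <- sim_truth(sigma_motor = 0, a1 = 0, a2 = 0, a0 = 0,
                     mu_rt = 1200)
  tr <- simulate_behavior(spec, truth, seed = 1)
  expect_equal(tr$rt, rep(1200, 40))
  expect_equal(tr$abs_error, rep(0, 40))
})

test_that("unstable generative dynamics are rejected with a diagnostic", {
  expect_error(sim_truth(a1 = 0.2), "unstable generative dynamics")
  expect_error(sim_truth(a1 = -2.5), "unstable generative dynamics")
})

test_that("identical spec, truth and seed reproduce the trial table exactly", {
  spec <- cohort_spec(n_per_group = 1, n_trials = 60, n_blocks = 2)
  truth <- sim_truth()
  a <- simulate_behavior(spec, truth, seed = 99)
  b <- simulate_behavior(spec, truth, seed = 99)
  expect_identical(a, b)
})

test_that("stimulus onsets increase by at least trial timeout plus min ITI", {
  spec <- cohort_spec(n_per_group = 1, n_trials = 120, n_blocks = 2)
  tr <- simulate_behavior(spec, sim_truth(), seed = 3)
  gaps <- diff(tr$stim_onset)
  expect_true(all(gaps >= spec$trial_timeout + spec$iti_range[1] - 1e-9))
  expect_true(all(gaps[tr$block[-1] == tr$block[-120]] <=
                    spec$trial_timeout + spec$iti_range[2] + 1e-9))
})

test_that("adjustment fit recovers the generative coefficient at large n", {
  spec <- cohort_spec(n_per_group = 1, n_trials = 10000, n_blocks = 2,
                      effects = NULL)
  truth <- sim_truth(a2 = -4e-4)
  tr <- simulate_behavior(spec, truth, seed = 11)
  fit <- fit_adjustment_model(tr)
  expect_lt(abs(fit$beta2 - truth$a2), 3 * fit$se2)
  expect_lt(abs(fit$beta1 - truth$a1), 3 * fit$se1)
})

test_that("null forward model yields a constant trace at full confidence", {
  spec <- cohort_spec(n_per_group = 1, n_trials = 10, n_blocks = 1)
  truth <- quiet_truth(g_task = 0, g_fb = 0, g_err = 0, tonic = 4)
  tr <- simulate_behavior(spec, truth, seed = 5)
  sm <- simulate_pupil(tr, truth)
  expect_equal(sm$diam_left, rep(4, nrow(sm)))
  expect_equal(sm$diam_right, rep(4, nrow(sm)))
  expect_true(all(sm$conf_left == 1) && all(sm$conf_right == 1))
})

test_that("noise-free forward model equals the closed-form composition", {
  spec <- cohort_spec(n_per_group = 1, n_trials = 12, n_blocks = 1)
  truth <- quiet_truth()
  tr <- simulate_behavior(spec, truth, seed = 6)
  sm <- simulate_pupil(tr, truth)
  area <- pupil_kernel_integral(Inf, truth$kernel_n, truth$kernel_tmax)
  expected <- rep(truth$tonic, nrow(sm))
  for (i in seq_len(nrow(tr))) {
    on <- tr$stim_onset[i] / 1000
    resp <- on + tr$rt[i] / 1000
    expected <- expected + truth$g_task / area *
      (pupil_kernel_integral(sm$t - on, truth$kernel_n, truth$kernel_tmax) -
         pupil_kernel_integral(sm$t - resp, truth$kernel_n,
                               truth$kernel_tmax)) +
      (truth$g_fb + truth$g_err * tr$abs_error[i]) *
        pupil_kernel(sm$t - resp, truth$kernel_n, truth$kernel_tmax)
  }
  expect_equal(sm$diam_left, expected, tolerance = 1e-12)
})

test_that("blink artifacts leave samples outside flagged intervals intact", {
  spec <- cohort_spec(n_per_group = 1, n_trials = 20, n_blocks = 1)
  truth_clean <- quiet_truth()
  truth_blink <- quiet_truth(artifact_rate = 15)
  tr <- simulate_behavior(spec, truth_clean, seed = 7)
  set.seed(21)
  clean <- simulate_pupil(tr, truth_clean)
  set.seed(21)
  noisy <- simulate_pupil(tr, truth_blink)
  ok <- noisy$conf_left == 1
  expect_gt(mean(!ok), 0)
  expect_equal(noisy$diam_left[ok], clean$diam_left[ok])
})

test_that("low-confidence fraction matches the blink process expectation", {
  spec <- cohort_spec(n_per_group = 1, n_trials = 100, n_blocks = 1)
  truth <- quiet_truth(artifact_rate = 6, artifact_asym = 1)
  tr <- simulate_behavior(spec, truth, seed = 8)
  set.seed(8)
  sm <- simulate_pupil(tr, truth)
  frac <- mean(sm$conf_left < 0.6)
  # expectation: rate/60 * (E[lognormal duration] + one extra edge sample);
  # the SD is that of the compound Poisson count of flagged samples (blink
  # clusters), which exceeds the naive binomial SD
  e_dur <- 0.150 * exp(0.5^2 / 2)
  p_exp <- 6 / 60 * (e_dur + 1 / 60)
  n <- nrow(sm)
  lam <- 6 / 60 * n / 60
  e_x <- p_exp * n / lam
  var_dur_smp <- (exp(0.25) - 1) * e_dur^2 * 60^2
  sd_frac <- sqrt(lam * (e_x^2 + var_dur_smp)) / n
  expect_lt(abs(frac - p_exp), 3 * sd_frac)
  # the right eye accumulates more artifacts (eye-selection asymmetry)
  truth2 <- quiet_truth(artifact_rate = 6, artifact_asym = 3)
  set.seed(9)
  sm2 <- simulate_pupil(tr, truth2)
  expect_gt(mean(sm2$conf_right < 0.6), mean(sm2$conf_left < 0.6))
})

test_that("cohort writer produces complete, re-readable datasets", {
  dir <- file.path(tempdir(), "synthgen-cohort")
  unlink(dir, recursive = TRUE)
  spec <- cohort_spec(n_per_group = 12, n_trials = 120, n_blocks = 2)
  truth <- sim_truth(seed = 4L)
  ledger <- simulate_cohort(spec, truth, dir, with_pupil = FALSE)
  tf <- list.files(dir, pattern = "^trials_")
  expect_length(tf, 48)
  rows <- vapply(tf, function(f) nrow(read_trials(file.path(dir, f))),
                 integer(1))
  expect_true(all(rows == 120))
  reread <- read_truth_ledger(dir)
  expect_equal(reread$truth[names(unclass(truth))], unclass(truth),
               ignore_attr = TRUE)
  expect_equal(reread$seed, 4L)
  # refusal to clobber an existing dataset
  expect_error(simulate_cohort(spec, truth, dir), "not empty")
  unlink(dir, recursive = TRUE)
})
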