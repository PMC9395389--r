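make_samples <- function(n, conf_left = 1, conf_right = 1) {
  data.frame(t = (seq_len(n) - 1) / 60, diam_left = 4, conf_left = conf_left,
             diam_right = 4, conf_right = conf_right, block = 1L)
}

test_that("eye selection maximizes the high-quality sample fraction", {
  expect_equal(select_eye(make_samples(100, conf_left = 0.9,
                                       conf_right = 0.5)), "left")
  s <- make_samples(100)
  s$conf_left <- c(rep(0.9, 80), rep(0.3, 20))
  s$conf_right <- c(rep(0.9, 95), rep(0.3, 5))
  expect_equal(select_eye(s), "right")
  expect_equal(select_eye(make_samples(100, conf_left = 0.8,
                                       conf_right = 0.8)), "left")
  expect_warning(eye <- select_eye(make_samples(10, conf_left = 0.1,
                                                conf_right = 0.2)),
                 "below the confidence threshold")
  expect_equal(eye, "left")
})

test_that("artifact detection applies confidence and derivative criteria", {
  n <- 60
  trace <- data.frame(t = (1:n) / 60, value = 10, conf = 1, block = 1L)
  det <- detect_artifacts(trace)
  expect_false(any(det$mask))
  expect_equal(nrow(det$intervals), 0)

  trace$conf[17] <- 0.5
  det <- detect_artifacts(trace)
  expect_equal(which(det$mask), 17L)

  # a single step excursion: the two samples its differences touch exceed
  # 4 * SD(diff) = 4 * sqrt(200/58) ~ 7.4 < 10
  trace2 <- data.frame(t = (1:n) / 60, value = c(rep(10, 29), 20, rep(10, 30)),
                       conf = 1, block = 1L)
  det2 <- detect_artifacts(trace2)
  expect_equal(which(det2$mask), c(30L, 31L))
  expect_equal(det2$intervals$duration, 2 / 60)
})

test_that("confidence-flagged samples are excluded from the derivative SD", {
  # a huge excursion with low confidence must not inflate the SD and hide
  # a smaller genuine jump elsewhere
  n <- 120
  v <- rep(10, n); v[40] <- 400; v[80] <- 15
  conf <- rep(1, n); conf[39:41] <- 0.1
  det <- detect_artifacts(data.frame(t = (1:n) / 60, value = v, conf = conf,
                                     block = 1L))
  expect_true(all(c(80L, 81L) %in% which(det$mask)))
})

test_that("interpolation fills interior gaps linearly and edges by extension", {
  tr <- data.frame(t = 1:3 / 60, value = c(1, 100, 3), block = 1L)
  expect_equal(interpolate_artifacts(tr, c(FALSE, TRUE, FALSE)), c(1, 2, 3))
  tr2 <- data.frame(t = 1:4 / 60, value = c(9, 9, 5, 7), block = 1L)
  expect_equal(interpolate_artifacts(tr2, c(TRUE, TRUE, FALSE, FALSE)),
               c(5, 5, 5, 7))
  tr3 <- data.frame(t = 1:5 / 60, value = rnorm(5), block = 1L)
  expect_equal(interpolate_artifacts(tr3, rep(FALSE, 5)), tr3$value)
})

test_that("the band-pass filter is linear and annihilates DC", {
  set.seed(1)
  x <- rnorm(2000); y <- rnorm(2000)
  fx <- bandpass_filter(x); fy <- bandpass_filter(y)
  fxy <- bandpass_filter(2 * x - 3 * y)
  expect_lt(max(abs(fxy - (2 * fx - 3 * fy))), 1e-9 * max(abs(fxy)))
  const <- bandpass_filter(rep(5, 3000))
  expect_lt(max(abs(const)), 5e-6)
  expect_error(bandpass_filter(rnorm(20)), "block too short")
  expect_error(bandpass_filter(rnorm(1000), lp = 40), "Nyquist")
})

test_that("sinusoid gains match the analytic zero-phase Butterworth response", {
  fs <- 60
  t <- (0:35999) / fs
  core <- 6001:30000  # central portion, away from edge transients
  warp <- function(f) tan(pi * f / fs)
  gain_ana <- function(f, hp = 0.06, lp = 6, order = 3) {
    gh <- 1 / (1 + (warp(hp) / warp(f))^(2 * order))
    gl <- 1 / (1 + (warp(f) / warp(lp))^(2 * order))
    gh * gl  # amplitude gain of the forward-backward (squared) response
  }
  for (f in c(0.05, 1, 4)) {
    y <- bandpass_filter(sin(2 * pi * f * t))
    meas <- sqrt(2 * mean(y[core]^2))
    expect_equal(meas, gain_ana(f), tolerance = 0.02)
  }
})

test_that("median normalization is exact, scale-invariant and guarded", {
  pre <- c(2, 4, 6, 4, 2, 10, 10, 30, 10, 10)
  blk <- rep(1:2, each = 5)
  out <- normalize_to_median(pre, pre, blk)
  expect_equal(as.numeric(tapply(out, blk, median)), c(100, 100))
  # block {2,4,6,4,2} has median 4, so a filtered value of 4 maps to 100
  expect_equal(as.numeric(normalize_to_median(rep(4, 5), pre[1:5],
                                              rep(1, 5))), rep(100, 5))
  filt <- rnorm(10)
  expect_equal(as.numeric(normalize_to_median(filt, pre, blk)),
               as.numeric(normalize_to_median(filt, 2 * pre, blk) * 2))
  expect_error(normalize_to_median(filt, pre - 5, blk), "nonpositive")
})

test_that("preprocessing a null recording returns a flat zero trace", {
  spec <- cohort_spec(n_per_group = 1, n_trials = 20, n_blocks = 2)
  truth <- quiet_truth(g_task = 0, g_fb = 0, g_err = 0)
  tr <- simulate_behavior(spec, truth, seed = 2)
  sm <- simulate_pupil(tr, truth)
  ct <- preprocess_pupil(sm)
  expect_false(any(ct$artifact_mask))
  expect_lt(max(abs(ct$value)), 1e-5)
  expect_equal(as.numeric(attr(ct, "medians")), c(4, 4))
  # determinism
  ct2 <- preprocess_pupil(sm)
  expect_identical(ct, ct2)
})

test_that("a one-second blink is flagged, interpolated and QC-reported", {
  n <- 3600
  s <- make_samples(n)
  blink <- 1000:1059  # 60 samples = 1 s at 60 Hz
  s$diam_left[blink] <- 2.8
  s$conf_left[blink] <- 0.1
  s$diam_right <- s$diam_left; s$conf_right <- s$conf_left
  ct <- preprocess_pupil(s)
  expect_true(all(ct$artifact_mask[blink]))
  qc <- attr(ct, "qc")
  expect_equal(qc$n_long_intervals, 1)
  iv <- attr(ct, "intervals")
  expect_true(any(iv$duration > 0.75))
})

test_that("lowering the confidence threshold never adds flagged samples", {
  spec <- cohort_spec(n_per_group = 1, n_trials = 30, n_blocks = 1)
  truth <- sim_truth(artifact_rate = 15)
  tr <- simulate_behavior(spec, truth, seed = 13)
  set.seed(13)
  sm <- simulate_pupil(tr, truth)
  trace <- data.frame(t = sm$t, value = sm$diam_left, conf = sm$conf_left,
                      block = sm$block)
  m_hi <- detect_artifacts(trace, conf_threshold = 0.6)$mask
  for (thr in c(0.4, 0.2, 0.05)) {
    m_lo <- detect_artifacts(trace, conf_threshold = thr)$mask
    expect_true(all(m_hi | !m_lo))
  }
})

test_that("a fully artefactual block is marked unusable", {
  s <- make_samples(4000)
  s$block <- rep(1:2, each = 2000)
  s$conf_left[s$block == 2] <- 0.1
  s$conf_right[s$block == 2] <- 0.1
  ct <- preprocess_pupil(s)
  qc <- attr(ct, "qc")
  expect_false(qc$usable[qc$block == 2])
  expect_true(all(ct$block == 1))
})
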