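#' Ground-truth parameters for the forward simulator
#'
#' Bundles every generative parameter of the synthetic cohort: the behavioral
#' trial-to-trial dynamics (mean RT, motor noise, intercept/lag/adjustment
#' coefficients of the generative twin of the analysis regression), the pupil
#' forward model (tonic level, task- and feedback-evoked gains, impulse
#' response shape, drift and measurement noise), and the blink-artifact
#' process. The behavioral coefficients live on the same scale as the
#' analysis model fitted by [fit_adjustment_model()], so recovery can be
#' checked directly against this object.
#'
#' @param mu_rt Mean response time the dynamics are anchored to (ms).
#' @param sigma_motor SD of trial-wise motor noise (ms).
#' @param a1 Generative coefficient on the previous RT (unitless). `1 + a1`
#'   is approximately the lag-1 autocorrelation of the RT series; the default
#'   -0.8 yields the weak positive autocorrelation typical of produced
#'   interval series.
#' @param a2 Generative adjustment coefficient (1/ms), applied to
#'   `RT[t-1] * |error|[t-1]` exactly as in the analysis model. Negative
#'   values produce error-driven speeding after slow responses.
#' @param a0 Generative intercept (ms). If `NULL` it is chosen so that
#'   `mu_rt` is the approximate fixed point of the dynamics.
#' @param tonic Baseline pupil diameter (arbitrary units, > 0).
#' @param g_task Plateau amplitude of the task-evoked component (a.u.): the
#'   asymptotic response to a long stimulus-to-response boxcar drive.
#' @param g_fb Feedback-evoked response amplitude at zero error (a.u.).
#' @param g_err Additional feedback gain per ms of absolute error (a.u./ms).
#' @param kernel_n,kernel_tmax Shape and peak-time (s) of the pupil impulse
#'   response, see [pupil_kernel()].
#' @param drift_sd Stationary SD of the slow shared drift (a.u.).
#' @param drift_tau Time constant of the drift process (s).
#' @param noise_sd SD of per-eye white measurement noise (a.u.).
#' @param artifact_rate Expected blink events per minute (left eye); the
#'   right eye uses `artifact_rate * artifact_asym` so that eye selection by
#'   sample quality has a correct answer.
#' @param artifact_asym Multiplier on `artifact_rate` for the right eye.
#' @param seed Integer seed stored with the truth (used by
#'   [simulate_cohort()] as the master seed).
#'
#' @return A list of class `sim_truth`.
#' @export
sim_truth <- function(mu_rt = 1200, sigma_motor = 80, a1 = -0.8, a2 = -4e-4,
                      a0 = NULL, tonic = 4, g_task = 0.2, g_fb = 0.1,
                      g_err = 0.002, kernel_n = 10.1, kernel_tmax = 0.93,
                      drift_sd = 0.08, drift_tau = 20, noise_sd = 0.03,
                      artifact_rate = 12, artifact_asym = 2, seed = 1L) {
  stopifnot(sigma_motor >= 0, tonic > 0, artifact_rate >= 0,
            kernel_tmax > 0, kernel_n > 0, drift_sd >= 0, noise_sd >= 0,
            artifact_asym > 0)
  truth <- list(mu_rt = mu_rt, sigma_motor = sigma_motor,
                a0 = a0, a1 = a1, a2 = a2,
                tonic = tonic, g_task = g_task, g_fb = g_fb, g_err = g_err,
                kernel_n = kernel_n, kernel_tmax = kernel_tmax,
                drift_sd = drift_sd, drift_tau = drift_tau,
                noise_sd = noise_sd, artifact_rate = artifact_rate,
                artifact_asym = artifact_asym, seed = as.integer(seed))
  if (is.null(truth$a0)) truth$a0 <- solve_fixed_point_intercept(truth)
  class(truth) <- "sim_truth"
  validate_truth_dynamics(truth)
  truth
}

# Intercept making mu_rt the approximate fixed point of the RT dynamics:
# 0 = a0 + a1*mu + a2*mu*E|error| at stationarity. E|error| is approximated
# by the folded-normal mean of the stationary RT distribution.
solve_fixed_point_intercept <- function(truth) {
  e_abs <- expected_abs_error(truth)
  -(truth$a1 * truth$mu_rt + truth$a2 * truth$mu_rt * e_abs)
}

expected_abs_error <- function(truth) {
  rho0 <- 1 + truth$a1
  sd_st <- truth$sigma_motor / sqrt(max(1 - min(rho0^2, 0.95), 0.05))
  sqrt(2 / pi) * sd_st
}

# Reject configurations whose linearized dynamics are non-contracting:
# the effective AR coefficient |1 + a1 + a2 * E|error|| must stay below 1.
# The marginal case |rho| = 1 is allowed only for noise-free dynamics
# (a bounded trajectory pinned to the fixed point).
validate_truth_dynamics <- function(truth) {
  rho_eff <- 1 + truth$a1 + truth$a2 * expected_abs_error(truth)
  if (truth$sigma_motor == 0 && abs(rho_eff) <= 1) return(invisible(truth))
  if (abs(rho_eff) >= 1) {
    stop(sprintf(paste0("unstable generative dynamics: effective AR ",
                        "coefficient |1 + a1 + a2*E|error|| = %.3f >= 1; ",
                        "choose a1 in (-2, 0) with |a2| small"),
                 abs(rho_eff)))
  }
  invisible(truth)
}

#' Cohort design for the synthetic experiment
#'
#' Describes the study layout emulated by the simulator: two groups measured
#' in two sessions of 120 trials split over two blocks, with a 1200-ms target
#' interval, feedback clamped to 600--1800 ms, trials timing out at 2000 ms
#' and intertrial intervals jittered between 1700 and 2300 ms.
#'
#' @param n_per_group Participants per group.
#' @param groups Group labels; the first is treated as the patient group.
#' @param sessions Session labels (within-subject factor).
#' @param n_trials Trials per session (must be divisible by `n_blocks`).
#' @param n_blocks Blocks per session.
#' @param iti_range Intertrial jitter bounds (ms).
#' @param trial_timeout Automatic trial end (ms).
#' @param target Target interval (ms).
#' @param feedback_range Bounds of the displayed feedback scale (ms).
#' @param block_gap Pause inserted between blocks (ms).
#' @param first_onset Session-clock time of the first stimulus (ms); leaves
#'   room for the pre-stimulus baseline and filter margins.
#' @param effects Per group-by-session multiplicative shifts of truth
#'   parameters, as `effects[[group]][[session]] = c(field = multiplier)`.
#'   `NULL` means a null cohort (no group or session effects). See
#'   [default_group_session_effects()].
#'
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_group = 12, groups = c("patient", "control"),
                        sessions = c("1", "2"), n_trials = 120L,
                        n_blocks = 2L, iti_range = c(1700, 2300),
                        trial_timeout = 2000, target = 1200,
                        feedback_range = c(600, 1800), block_gap = 20000,
                        first_onset = 3000,
                        effects = default_group_session_effects()) {
  stopifnot(n_per_group >= 1, length(groups) == 2, length(sessions) >= 1,
            n_trials >= 2, n_blocks >= 1, n_trials %% n_blocks == 0,
            length(iti_range) == 2, iti_range[1] < iti_range[2],
            iti_range[1] >= 0, trial_timeout > 0, target > 0,
            feedback_range[1] < feedback_range[2], block_gap >= 0,
            first_onset > 500)
  spec <- list(n_per_group = as.integer(n_per_group), groups = groups,
               sessions = as.character(sessions),
               n_trials = as.integer(n_trials),
               n_blocks = as.integer(n_blocks), iti_range = iti_range,
               trial_timeout = trial_timeout, target = target,
               feedback_range = feedback_range, block_gap = block_gap,
               first_onset = first_onset, effects = effects)
  class(spec) <- "cohort_spec"
  spec
}

#' Default group-by-session parameter shifts
#'
#' Emulates a patient group whose performance and pupil sensitivity degrade
#' in the second (medication-withdrawn) session: noisier timing, weakened
#' error-driven adjustment and reduced error-scaled feedback response, plus
#' a modestly attenuated task-evoked response in session 1. Controls are
#' unchanged. Multipliers apply to the named `sim_truth` fields.
#'
#' @return Nested list keyed by group then session.
#' @export
default_group_session_effects <- function() {
  list(patient = list(`1` = c(g_task = 0.80),
                      `2` = c(sigma_motor = 1.25, a2 = 0.40,
                              g_task = 0.95, g_err = 0.60)))
}

# Apply multiplicative cell effects to a truth object (a0 is preserved, so
# shifted cells may drift slightly off the nominal fixed point, as real
# sessions would).
apply_cell_effects <- function(truth, spec, group, session) {
  eff <- spec$effects[[group]][[as.character(session)]]
  if (is.null(eff)) return(truth)
  for (nm in names(eff)) {
    if (is.null(truth[[nm]])) stop("unknown truth field in effects: ", nm)
    truth[[nm]] <- truth[[nm]] * eff[[nm]]
  }
  validate_truth_dynamics(truth)
  truth
}

#' Simulate one participant-session of timing behavior
#'
#' Generates an RT sequence from the generative twin of the analysis model:
#' `RT[t] = RT[t-1] + a0 + a1*RT[t-1] + a2*RT[t-1]*|error|[t-1] + eps[t]`
#' with `eps ~ N(0, sigma_motor^2)`; the first trial of each block is drawn
#' from `N(mu_rt, sigma_motor^2)`. Responses exceeding the trial timeout are
#' truncated to the timeout for the dynamics and flagged as missing (lapses);
#' RTs are clipped below at 1 ms. Stimulus onsets accumulate the trial
#' timeout plus uniform ITI jitter, with a fixed pause between blocks.
#'
#' @param spec A [cohort_spec()].
#' @param truth A [sim_truth()].
#' @param seed Optional integer; if given, the RNG is seeded before drawing.
#'
#' @return A trial table (see [compute_errors()]) with columns `trial_index`,
#'   `block`, `stim_onset` (ms), `rt` (ms, `NA` for lapses), and the derived
#'   error/feedback columns.
#' @export
simulate_behavior <- function(spec, truth, seed = NULL) {
  stopifnot(inherits(spec, "cohort_spec"), inherits(truth, "sim_truth"))
  validate_truth_dynamics(truth)
  if (!is.null(seed)) set.seed(seed)
  n <- spec$n_trials
  per_block <- n %/% spec$n_blocks
  eps <- stats::rnorm(n, 0, truth$sigma_motor)
  iti <- stats::runif(n, spec$iti_range[1], spec$iti_range[2])
  rt <- numeric(n)
  missing <- logical(n)
  prev <- NA_real_
  for (t in seq_len(n)) {
    if ((t - 1L) %% per_block == 0L) {
      val <- truth$mu_rt + eps[t]
    } else {
      abs_prev <- abs(prev - spec$target)
      val <- prev + truth$a0 + truth$a1 * prev +
        truth$a2 * prev * abs_prev + eps[t]
    }
    if (val > spec$trial_timeout) {
      val <- spec$trial_timeout
      missing[t] <- TRUE
    }
    if (val < 1) val <- 1
    rt[t] <- val
    prev <- val
  }
  block <- rep(seq_len(spec$n_blocks), each = per_block)
  onset <- numeric(n)
  onset[1] <- spec$first_onset
  if (n > 1) {
    step <- spec$trial_timeout + iti[seq_len(n - 1)]
    step <- step + ifelse(diff(block) > 0, spec$block_gap, 0)
    onset[-1] <- spec$first_onset + cumsum(step)
  }
  trials <- data.frame(trial_index = seq_len(n), block = block,
                       stim_onset = onset,
                       rt = ifelse(missing, NA_real_, rt))
  trials <- compute_errors(trials, target = spec$target,
                           feedback_range = spec$feedback_range)
  attr(trials, "trial_timeout") <- spec$trial_timeout
  trials
}

#' Pupil impulse response (unit peak)
#'
#' Gamma-family kernel `K(t) = (t/tmax)^n * exp(n * (1 - t/tmax))`, the
#' standard psychophysiological impulse response, normalized to peak 1 at
#' `t = tmax`. Zero for `t <= 0`.
#'
#' @param t Time (s), vectorized.
#' @param n Shape parameter.
#' @param tmax Peak latency (s).
#' @return Kernel values.
#' @export
pupil_kernel <- function(t, n = 10.1, tmax = 0.93) {
  stopifnot(n > 0, tmax > 0)
  out <- numeric(length(t))
  pos <- which(t > 0)
  x <- t[pos] / tmax
  out[pos] <- exp(n * (log(x) + 1 - x))
  out
}

#' Integral of the unit-peak pupil kernel
#'
#' Closed form of `\int_0^t K(s) ds` via the regularized incomplete gamma
#' function, used to evaluate boxcar-convolved task drives exactly.
#'
#' @inheritParams pupil_kernel
#' @return Integral values (s); `pupil_kernel_integral(Inf)` is the total
#'   kernel area.
#' @export
pupil_kernel_integral <- function(t, n = 10.1, tmax = 0.93) {
  stopifnot(n > 0, tmax > 0)
  log_scale <- lgamma(n + 1) + log(tmax) - (n + 1) * log(n) + n
  exp(log_scale) * stats::pgamma(pmax(t, 0) * n / tmax, n + 1)
}

#' Simulate a binocular 60-Hz pupil recording for one session
#'
#' Forward model per sample:
#' `diam(t) = tonic + drift(t) + task(t) + feedback(t) + noise`, where the
#' task component is the unit-area kernel convolved with a boxcar from
#' stimulus onset to response (plateau `g_task` for long drives, evaluated
#' in closed form via [pupil_kernel_integral()]), and the feedback component
#' is `(g_fb + g_err * |error|) * K(t - t_response)`. Drift is a shared
#' Ornstein-Uhlenbeck process; each eye adds independent white noise and an
#' independent Poisson stream of blink artifacts (30% diameter drop with
#' 50-ms ramps, log-normal duration with median 150 ms, confidence forced to
#' 0.1 for the whole blink). The right eye uses `artifact_rate *
#' artifact_asym`. On lapse trials (missing RT) the task drive runs to the
#' trial timeout and no feedback response is generated.
#'
#' @param trials Trial table from [simulate_behavior()].
#' @param truth A [sim_truth()].
#' @param fs Sampling rate (Hz).
#' @param pre_s,post_s Recording margins before the first stimulus and after
#'   the last trial (s).
#' @param trial_timeout Trial timeout (ms); defaults to the value recorded
#'   on `trials`.
#'
#' @return A samples table: `t` (s), `diam_left`, `conf_left`, `diam_right`,
#'   `conf_right`, `block`.
#' @export
simulate_pupil <- function(trials, truth, fs = 60, pre_s = 2.5, post_s = 4,
                           trial_timeout = NULL) {
  stopifnot(inherits(truth, "sim_truth"), nrow(trials) >= 1)
  if (is.null(trial_timeout)) {
    trial_timeout <- attr(trials, "trial_timeout")
    if (is.null(trial_timeout)) trial_timeout <- 2000
  }
  onset_s <- trials$stim_onset / 1000
  end_s <- onset_s + ifelse(is.na(trials$rt), trial_timeout, trials$rt) / 1000
  n_tr <- nrow(trials)
  if (n_tr > 1) {
    bad <- which(onset_s[-1] < end_s[-n_tr] + 1e-9)
    if (length(bad)) {
      stop(sprintf("trial %d overlaps the response window of trial %d",
                   trials$trial_index[bad[1] + 1], trials$trial_index[bad[1]]))
    }
  }
  if (onset_s[1] - pre_s < -1e-9) pre_s <- onset_s[1]
  t0 <- onset_s[1] - pre_s
  t_end <- max(end_s) + post_s
  nsmp <- floor((t_end - t0) * fs) + 1L
  t <- t0 + (seq_len(nsmp) - 1L) / fs

  kern_support <- 8 * truth$kernel_tmax
  base <- rep(truth$tonic, nsmp)
  for (i in seq_len(n_tr)) {
    lo <- max(1L, floor((onset_s[i] - t0) * fs) + 1L)
    hi <- min(nsmp, ceiling((end_s[i] + kern_support - t0) * fs) + 1L)
    idx <- lo:hi
    if (truth$g_task != 0) {
      area <- pupil_kernel_integral(Inf, truth$kernel_n, truth$kernel_tmax)
      base[idx] <- base[idx] + truth$g_task / area *
        (pupil_kernel_integral(t[idx] - onset_s[i],
                               truth$kernel_n, truth$kernel_tmax) -
           pupil_kernel_integral(t[idx] - end_s[i],
                                 truth$kernel_n, truth$kernel_tmax))
    }
    if (!is.na(trials$rt[i]) && (truth$g_fb != 0 || truth$g_err != 0)) {
      amp <- truth$g_fb + truth$g_err * trials$abs_error[i]
      base[idx] <- base[idx] +
        amp * pupil_kernel(t[idx] - end_s[i], truth$kernel_n,
                           truth$kernel_tmax)
    }
  }
  if (truth$drift_sd > 0) {
    # discretized Ornstein-Uhlenbeck with a stationary start
    phi <- exp(-1 / (fs * truth$drift_tau))
    innov <- stats::rnorm(nsmp, 0, truth$drift_sd * sqrt(1 - phi^2))
    innov[1] <- stats::rnorm(1, 0, truth$drift_sd)
    base <- base + as.numeric(stats::filter(innov, phi, method = "recursive"))
  }

  make_eye <- function(rate) {
    d <- base
    if (truth$noise_sd > 0) d <- d + stats::rnorm(nsmp, 0, truth$noise_sd)
    conf <- rep(1, nsmp)
    dur_min <- (t_end - t0) / 60
    n_blinks <- stats::rpois(1, rate * dur_min)
    if (n_blinks > 0) {
      starts <- sort(stats::runif(n_blinks, t0, t_end))
      durs <- stats::rlnorm(n_blinks, log(0.150), 0.5)
      for (b in seq_len(n_blinks)) {
        lo <- floor((starts[b] - t0) * fs) + 1L
        hi <- floor((starts[b] + durs[b] - t0) * fs) + 1L
        lo <- max(1L, lo); hi <- min(nsmp, hi)
        if (lo > hi) next
        tau <- t[lo:hi] - starts[b]
        w <- pmax(0, pmin(1, tau / 0.05, (durs[b] - tau) / 0.05))
        d[lo:hi] <- d[lo:hi] * (1 - 0.3 * w)
        conf[lo:hi] <- 0.1
      }
    }
    list(d = d, conf = conf)
  }
  left <- make_eye(truth$artifact_rate)
  right <- make_eye(truth$artifact_rate * truth$artifact_asym)

  block <- assign_sample_blocks(t, trials, end_s)
  data.frame(t = t, diam_left = left$d, conf_left = left$conf,
             diam_right = right$d, conf_right = right$conf, block = block)
}

# Samples between blocks are split at the midpoint of the inter-block pause.
assign_sample_blocks <- function(t, trials, end_s) {
  blocks <- sort(unique(trials$block))
  if (length(blocks) == 1) return(rep(blocks, length(t)))
  bounds <- vapply(seq_len(length(blocks) - 1), function(i) {
    last_end <- max(end_s[trials$block == blocks[i]])
    next_on <- min(trials$stim_onset[trials$block == blocks[i + 1]]) / 1000
    (last_end + next_on) / 2
  }, numeric(1))
  blocks[findInterval(t, bounds) + 1L]
}

#' Simulate and write a complete synthetic cohort
#'
#' Draws per participant-session seeds from the master seed, applies the
#' group-by-session effects to the base truth, simulates behavior and the
#' binocular pupil stream for every participant and session, and writes the
#' dataset as delimited text: `trials_<participant>_s<session>.csv`,
#' `samples_<participant>_s<session>.csv`, `participants.csv` (with a
#' body-weight-normalized levodopa dose for patients), and `truth.json`, the
#' complete ground-truth ledger used by recovery tests.
#'
#' @param spec A [cohort_spec()].
#' @param base_truth A [sim_truth()]; per-cell effects from `spec$effects`
#'   are applied on top.
#' @param dir Output directory.
#' @param seed Master seed; defaults to `base_truth$seed`.
#' @param overwrite Refuse to write into an existing non-empty directory
#'   unless `TRUE`.
#' @param with_pupil Set `FALSE` to write behavior only (used by large
#'   behavioral calibration studies).
#'
#' @return Invisibly, the truth ledger (also written as `truth.json`).
#' @export
simulate_cohort <- function(spec, base_truth, dir, seed = base_truth$seed,
                            overwrite = FALSE, with_pupil = TRUE) {
  stopifnot(inherits(spec, "cohort_spec"), inherits(base_truth, "sim_truth"))
  if (dir.exists(dir) && length(dir(dir)) > 0 && !overwrite) {
    stop("output directory ", dir, " is not empty; use overwrite = TRUE")
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  participants <- unlist(lapply(spec$groups, function(g) {
    sprintf("%s%02d", g, seq_len(spec$n_per_group))
  }))
  groups <- rep(spec$groups, each = spec$n_per_group)
  n_ps <- length(participants) * length(spec$sessions)
  ps_seeds <- sample.int(.Machine$integer.max - 1L, n_ps)
  dose <- ifelse(groups == spec$groups[1],
                 round(stats::rlnorm(length(groups), log(7), 0.3), 2),
                 NA_real_)
  meta <- data.frame(participant = participants, group = groups,
                     dose_mg_per_kg = dose)
  data.table::fwrite(meta, file.path(dir, "participants.csv"))

  cell_seeds <- list()
  k <- 0L
  for (i in seq_along(participants)) {
    for (s in spec$sessions) {
      k <- k + 1L
      truth_cell <- apply_cell_effects(base_truth, spec, groups[i], s)
      set.seed(ps_seeds[k])
      trials <- simulate_behavior(spec, truth_cell)
      write_trials(trials, file.path(dir, sprintf("trials_%s_s%s.csv",
                                                  participants[i], s)))
      if (with_pupil) {
        samples <- simulate_pupil(trials, truth_cell)
        write_samples(samples, file.path(dir, sprintf("samples_%s_s%s.csv",
                                                      participants[i], s)))
      }
      cell_seeds[[sprintf("%s_s%s", participants[i], s)]] <- ps_seeds[k]
    }
  }
  ledger <- list(seed = as.integer(seed),
                 truth = unclass(base_truth),
                 spec = unclass(spec),
                 cell_seeds = cell_seeds,
                 with_pupil = with_pupil)
  jsonlite::write_json(ledger, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(ledger)
}

#' Read back the ground-truth ledger of a simulated cohort
#'
#' @param dir Cohort directory written by [simulate_cohort()].
#' @return The ledger list (`seed`, `truth`, `spec`, `cell_seeds`).
#' @export
read_truth_ledger <- function(dir) {
  path <- file.path(dir, "truth.json")
  if (!file.exists(path)) stop("no truth.json in ", dir)
  jsonlite::read_json(path, simplifyVector = TRUE)
}
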