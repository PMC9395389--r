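# Independent oracles and fixture builders shared across tests.

# Normal-equations OLS, independent of the package's fitting path.
ols_oracle <- function(X, y) {
  as.numeric(solve(t(X) %*% X, t(X) %*% y))
}

# Explicit sums-of-squares decomposition for a balanced 2 (group, between)
# x 2 (session, within) design, computed from cell and marginal means.
anova_ss_oracle <- function(d) {
  m <- mean(d$value)
  subj <- tapply(d$value, d$participant, mean)
  grp_of <- tapply(as.character(d$group), d$participant, unique)
  gm <- tapply(d$value, d$group, mean)
  sm <- tapply(d$value, d$session, mean)
  s <- length(unique(d$session))
  n_subj <- length(subj)
  n_g <- table(unlist(grp_of))
  ss_between <- s * sum((subj - m)^2)
  ss_group <- s * sum(n_g * (gm[names(n_g)] - m)^2)
  ss_subj_within <- ss_between - ss_group
  ss_session <- n_subj * sum((sm - m)^2)
  cells <- aggregate(value ~ group + session, d, mean)
  cells$n <- n_g[as.character(cells$group)]
  ss_cells <- sum(cells$n * (cells$value - m)^2)
  ss_inter <- ss_cells - ss_group - ss_session
  ss_total <- sum((d$value - m)^2)
  ss_err <- ss_total - ss_between - ss_session - ss_inter
  g <- length(n_g)
  list(
    F_group = (ss_group / (g - 1)) / (ss_subj_within / (n_subj - g)),
    F_session = (ss_session / (s - 1)) / (ss_err / ((n_subj - g) * (s - 1))),
    F_inter = (ss_inter / ((g - 1) * (s - 1))) /
      (ss_err / ((n_subj - g) * (s - 1))),
    pes_group = ss_group / (ss_group + ss_subj_within),
    pes_session = ss_session / (ss_session + ss_err),
    pes_inter = ss_inter / (ss_inter + ss_err))
}

random_balanced_design <- function(n_per_group = 6) {
  n <- 2 * n_per_group
  data.frame(participant = rep(sprintf("p%02d", 1:n), each = 2),
             group = rep(c("a", "b"), each = 2 * n_per_group),
             session = rep(c("1", "2"), n),
             value = rnorm(2 * n))
}

# A trial table with arbitrary rt / abs_error columns (single block).
make_trials <- function(rt, abs_error = abs(rt - 1200), block = 1L) {
  data.frame(trial_index = seq_along(rt), block = block,
             stim_onset = seq_along(rt) * 4500, rt = rt,
             signed_error = rt - 1200, abs_error = abs_error,
             feedback_value = pmin(1800, pmax(600, rt)),
             valid = TRUE)
}

# Constructed 120-trial session with exactly 7 designed rejection-rule
# violations (2 fast RTs, 3 epochs > 50% artefactual, 2 overlaps with an
# artifact interval > 750 ms), on a constant trace so the categories cannot
# interact. Returns everything needed to run extract + reject.
build_rejection_fixture <- function(fs = 60) {
  n <- 120
  onset <- 3000 + (seq_len(n) - 1) * 4500
  rt <- rep(1200, n)
  rt[c(10, 50)] <- 350
  trials <- compute_errors(data.frame(trial_index = seq_len(n), block = 1L,
                                      stim_onset = onset, rt = rt))
  t <- seq(0, max(onset + rt) / 1000 + 2, by = 1 / fs)
  conf <- rep(1, length(t))
  lock_idx <- findInterval((onset + rt) / 1000 + 1e-9, t)
  for (tr in c(20, 60, 100)) {   # 76 of 150 epoch samples, in short chunks
    s0 <- lock_idx[tr] - 90
    conf[s0 + 0:39] <- 0.1
    conf[s0 + 45 + 0:35] <- 0.1
  }
  for (tr in c(80, 110)) {       # 48-sample (800 ms) interval, 8 samples in
    s0 <- lock_idx[tr] - 90
    conf[(s0 - 40):(s0 + 7)] <- 0.1
  }
  trace_raw <- data.frame(t = t, value = 4, conf = conf, block = 1L)
  det <- detect_artifacts(trace_raw, fs = fs)
  trace <- data.frame(t = t, value = 4, artifact_mask = det$mask, block = 1L)
  list(trace = trace, trials = trials, intervals = det$intervals)
}

# A synthetic feedback-mode epoch set with a given data matrix and
# per-trial absolute errors, all trials kept.
make_epochs <- function(data, abs_error, time = (0:(ncol(data) - 1)) / 60) {
  structure(list(spec = feedback_epoch_spec(), fs = 60, time = time,
                 data = data, mask = matrix(FALSE, nrow(data), ncol(data)),
                 baseline = rep(0, nrow(data)), abs_error = abs_error,
                 rt = rep(1200, nrow(data)), lock_t = rep(0, nrow(data)),
                 kept = rep(TRUE, nrow(data)),
                 reason = rep("ok", nrow(data)),
                 participant = "p01", session = "1"),
            class = "epoch_set")
}

# Minimal truth with all stochastic pupil components switched off
# (individual components can be switched back on via ...).
quiet_truth <- function(...) {
  args <- list(drift_sd = 0, noise_sd = 0, artifact_rate = 0)
  user <- list(...)
  args[names(user)] <- user
  do.call(sim_truth, args)
}
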