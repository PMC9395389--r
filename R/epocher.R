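#' Epoch specification
#'
#' Defines an event-locked segmentation: the epoch window relative to the
#' lock event (the response, which coincides with feedback onset), and the
#' 400-ms baseline window with its own lock. Two standard modes:
#' [task_epoch_spec()] segments \[-1500, 1000\] ms around the response with a
#' pre-*stimulus* baseline (\[-400, 0\] ms), and [feedback_epoch_spec()]
#' segments \[0, 1500\] ms with a pre-*response* baseline.
#'
#' Sample windows are half-open `[start, end)` on the native 60-Hz grid, and
#' lock times map to the nearest sample at or before the event, giving
#' unambiguous sample counts (e.g. 150 samples for the task window).
#'
#' @param lock `"response"` or `"feedback"` (identical event time).
#' @param window Epoch window, ms relative to the lock, `c(start, end)`.
#' @param baseline_window Baseline window (ms, must span 400 ms).
#' @param baseline_lock `"stimulus"` or `"response"`.
#' @return An object of class `epoch_spec`.
#' @export
epoch_spec <- function(lock = c("response", "feedback"),
                       window, baseline_window = c(-400, 0),
                       baseline_lock = c("stimulus", "response")) {
  lock <- match.arg(lock)
  baseline_lock <- match.arg(baseline_lock)
  stopifnot(length(window) == 2, window[1] < window[2],
            length(baseline_window) == 2,
            abs(diff(baseline_window) - 400) < 1e-9)
  out <- list(lock = lock, window = window,
              baseline_window = baseline_window,
              baseline_lock = baseline_lock)
  class(out) <- "epoch_spec"
  out
}

#' @rdname epoch_spec
#' @export
task_epoch_spec <- function() {
  epoch_spec("response", c(-1500, 1000), c(-400, 0), "stimulus")
}

#' @rdname epoch_spec
#' @export
feedback_epoch_spec <- function() {
  epoch_spec("feedback", c(0, 1500), c(-400, 0), "response")
}

# Sample offsets k (relative to the lock sample) with k/fs in [w1, w2) ms.
window_offsets <- function(window_ms, fs) {
  k1 <- as.integer(ceiling(window_ms[1] * fs / 1000 - 1e-9))
  k2 <- as.integer(ceiling(window_ms[2] * fs / 1000 - 1e-9)) - 1L
  k1:k2
}

#' Extract event-locked, baseline-corrected epochs
#'
#' Cuts one epoch per trial from a cleaned trace: samples whose time
#' relative to the lock event falls in the half-open epoch window, minus the
#' per-trial scalar baseline (mean of the samples in the baseline window at
#' its own lock). Trials whose epoch or baseline extends beyond the
#' recording (or across a dropped block) are flagged unextractable; trials
#' without a response are flagged missing.
#'
#' @param trace A `clean_trace` from [preprocess_pupil()].
#' @param trials A trial table (needs `stim_onset`, `rt`, `abs_error`).
#' @param spec An [epoch_spec()].
#' @param fs Sampling rate (Hz).
#'
#' @return An object of class `epoch_set`: `time` (s relative to lock),
#'   `data` (trial x time matrix, % change), `mask` (artifact flags per
#'   epoch sample), `baseline`, `abs_error`, `rt`, `lock_t` (absolute lock
#'   sample time, s), `kept` (logical), `reason` (per-trial code), `spec`,
#'   `fs`, and `participant`/`session` slots filled by the pipeline.
#' @export
extract_epochs <- function(trace, trials, spec, fs = 60) {
  stopifnot(inherits(spec, "epoch_spec"), is.data.frame(trace),
            all(c("t", "value") %in% names(trace)))
  mask_col <- if ("artifact_mask" %in% names(trace)) trace$artifact_mask
  else rep(FALSE, nrow(trace))
  rel_k <- window_offsets(spec$window, fs)
  base_k <- window_offsets(spec$baseline_window, fs)
  nt <- nrow(trials)
  nT <- length(rel_k)
  data <- matrix(NA_real_, nt, nT)
  maskm <- matrix(NA, nt, nT)
  baseline <- rep(NA_real_, nt)
  lock_t <- rep(NA_real_, nt)
  kept <- rep(FALSE, nt)
  reason <- rep("ok", nt)
  tv <- trace$t
  n <- length(tv)
  tol <- 0.25 / fs
  for (i in seq_len(nt)) {
    if (is.na(trials$rt[i])) {
      reason[i] <- "rt_missing"
      next
    }
    t_resp <- (trials$stim_onset[i] + trials$rt[i]) / 1000
    t_base <- if (spec$baseline_lock == "stimulus")
      trials$stim_onset[i] / 1000 else t_resp
    li <- findInterval(t_resp + 1e-9, tv)
    bi <- findInterval(t_base + 1e-9, tv)
    idx <- li + rel_k
    bidx <- bi + base_k
    if (li < 1 || bi < 1 || any(idx < 1) || any(idx > n) ||
        any(bidx < 1) || any(bidx > n)) {
      reason[i] <- "unextractable"
      next
    }
    # guard against dropped blocks / grid gaps inside the windows
    if (max(abs(tv[idx] - (tv[li] + rel_k / fs))) > tol ||
        max(abs(tv[bidx] - (tv[bi] + base_k / fs))) > tol) {
      reason[i] <- "unextractable"
      next
    }
    baseline[i] <- mean(trace$value[bidx])
    data[i, ] <- trace$value[idx] - baseline[i]
    maskm[i, ] <- mask_col[idx]
    lock_t[i] <- tv[li]
    kept[i] <- TRUE
  }
  out <- list(spec = spec, fs = fs, time = rel_k / fs, data = data,
              mask = maskm, baseline = baseline,
              abs_error = trials$abs_error, rt = trials$rt,
              lock_t = lock_t, kept = kept, reason = reason,
              participant = NULL, session = NULL)
  class(out) <- "epoch_set"
  out
}

#' Apply the trial-rejection rules
#'
#' A trial is rejected iff its response time is below `rt_min` ms, or more
#' than `max_artifact_frac` of its epoch samples are artefactual (strict
#' inequality), or any single artifact interval strictly longer than
#' `long_artifact_ms` intersects the epoch window (any overlap, even one
#' sample). Rejection reasons are recorded; rejection is monotone in the
#' artifact mask.
#'
#' @param epochs An `epoch_set` from [extract_epochs()].
#' @param intervals Artifact intervals, e.g. `attr(trace, "intervals")`.
#' @param rt_min Minimum RT (ms).
#' @param max_artifact_frac Maximum tolerated flagged fraction.
#' @param long_artifact_ms Artifact-interval duration threshold (ms).
#' @return The `epoch_set` with updated `kept`/`reason`.
#' @export
reject_trials <- function(epochs, intervals = NULL, rt_min = 400,
                          max_artifact_frac = 0.5, long_artifact_ms = 750) {
  stopifnot(inherits(epochs, "epoch_set"))
  w <- epochs$spec$window / 1000
  for (i in which(epochs$kept)) {
    if (epochs$rt[i] < rt_min) {
      epochs$kept[i] <- FALSE
      epochs$reason[i] <- "rt_too_fast"
      next
    }
    if (mean(epochs$mask[i, ]) > max_artifact_frac) {
      epochs$kept[i] <- FALSE
      epochs$reason[i] <- "artifact_fraction"
      next
    }
    if (!is.null(intervals) && nrow(intervals)) {
      win_start <- epochs$lock_t[i] + w[1]
      win_end <- epochs$lock_t[i] + w[2]  # half-open upper edge
      long <- intervals$duration > long_artifact_ms / 1000
      overlap <- long & intervals$t_start < win_end - 1e-9 &
        intervals$t_end >= win_start - 1e-9
      if (any(overlap)) {
        epochs$kept[i] <- FALSE
        epochs$reason[i] <- "long_artifact"
      }
    }
  }
  epochs
}

#' Average the kept epochs of one participant-session
#'
#' Pointwise mean over kept trials. With zero kept trials the
#' participant-session is marked missing: `NULL` is returned with a warning
#' and the caller drops it listwise.
#'
#' @param epochs An `epoch_set` (after [reject_trials()]).
#' @return A `timecourse` object (`time`, `values`, `kind = "mean"`, `n`),
#'   or `NULL` if no trials survived.
#' @export
average_epochs <- function(epochs) {
  stopifnot(inherits(epochs, "epoch_set"))
  k <- which(epochs$kept)
  if (!length(k)) {
    warning("no kept trials: participant-session marked missing")
    return(NULL)
  }
  timecourse(epochs$time, colMeans(epochs$data[k, , drop = FALSE]),
             kind = "mean", n = length(k),
             participant = epochs$participant, session = epochs$session)
}

#' Construct a time-course object
#'
#' A statistic as a function of time relative to the lock event.
#'
#' @param time Time (s relative to lock).
#' @param values Statistic per time point.
#' @param kind One of `"mean"`, `"tstat"`, `"pvalue"`, `"beta"`.
#' @param n Number of contributing units.
#' @param participant,session Optional identifiers.
#' @return An object of class `timecourse`.
#' @export
timecourse <- function(time, values, kind = "mean", n = NA_integer_,
                       participant = NULL, session = NULL) {
  stopifnot(length(time) == length(values))
  if (kind == "pvalue" && any(values < 0 | values > 1, na.rm = TRUE)) {
    stop("p-values outside [0, 1]")
  }
  out <- list(time = time, values = values, kind = kind, n = n,
              participant = participant, session = session)
  class(out) <- "timecourse"
  out
}
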