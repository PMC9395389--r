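#' Time-resolved one-sample test of the group-average pupil response
#'
#' For each participant with a time course in every session, the session
#' curves are averaged; per time point, a two-sided one-sample t-test
#' against 0 is computed across participants (both groups pooled). The
#' maximal contiguous interval of pointwise-significant samples is reported.
#' Pointwise alpha with no correction across time points: the analysis
#' reports contiguous significant intervals, not familywise-corrected
#' claims (see the methods vignette).
#'
#' @param tcs List of `timecourse` objects (one per participant-session,
#'   with `participant` and `session` set), all on the same time grid.
#' @param alpha Pointwise significance level.
#'
#' @return A list of class `timewise_test`: `time`, `mean`, `t`, `p`, `n`
#'   (participants), `alpha`, `sig_mask`, `sig_interval` (start/end times of
#'   the longest significant run, or `NULL`), `flagged` (time points with
#'   zero variance, where p is undefined).
#' @export
timewise_one_sample <- function(tcs, alpha = 0.05) {
  stopifnot(length(tcs) > 0)
  parts <- vapply(tcs, function(x) as.character(x$participant), character(1))
  sess <- vapply(tcs, function(x) as.character(x$session), character(1))
  time <- tcs[[1]]$time
  all_sessions <- unique(sess)
  complete <- names(which(table(unique(data.frame(parts, sess))$parts) ==
                            length(all_sessions)))
  complete <- intersect(unique(parts), complete)
  if (length(complete) < 3) {
    stop("need at least 3 participants with every session")
  }
  M <- t(vapply(complete, function(p) {
    rows <- which(parts == p)
    colMeans(do.call(rbind, lapply(tcs[rows], function(x) x$values)))
  }, numeric(length(time))))
  n <- nrow(M)
  m <- colMeans(M)
  s <- apply(M, 2, stats::sd)
  flagged <- which(s == 0)
  # zero variance: t undefined unless the mean is also exactly 0
  tstat <- ifelse(s > 0, m / (s / sqrt(n)), ifelse(m == 0, 0, NA_real_))
  p <- 2 * stats::pt(-abs(tstat), df = n - 1)
  p[flagged] <- NA_real_
  sig <- !is.na(p) & p < alpha
  sig_interval <- NULL
  if (any(sig)) {
    r <- rle(sig)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    runs <- which(r$values)
    best <- runs[which.max(r$lengths[runs])]
    sig_interval <- c(start = time[starts[best]], end = time[ends[best]])
  }
  out <- list(time = time, mean = m, t = tstat, p = p, n = n, alpha = alpha,
              sig_mask = sig, sig_interval = sig_interval, flagged = flagged)
  class(out) <- "timewise_test"
  out
}

#' Time-resolved single-trial regression of pupil dilation on |error|
#'
#' For every time point of a feedback-locked epoch set, fits by OLS
#' `d ~ b0 + b1 * |error|` across the kept trials of one
#' participant-session, where `d` is the baseline-corrected per-trial pupil
#' dilation at that time point. `b1` (a.u. %/ms) indexes the sensitivity of
#' the feedback-evoked response to performance error.
#'
#' @param epochs An `epoch_set` (feedback mode, after rejection).
#' @return An object of class `error_regression` (`time`, `beta0`, `beta1`,
#'   `n`, `participant`, `session`), or `NULL` with a warning when fewer
#'   than 3 kept trials or constant |error| leave the regression undefined.
#' @export
timewise_error_regression <- function(epochs) {
  stopifnot(inherits(epochs, "epoch_set"))
  k <- which(epochs$kept)
  ae <- epochs$abs_error[k]
  if (length(k) < 3 || stats::sd(ae) == 0) {
    warning("error regression undefined: <3 kept trials or constant |error|")
    return(NULL)
  }
  X <- cbind(1, ae)
  Y <- epochs$data[k, , drop = FALSE]
  B <- solve(crossprod(X), crossprod(X, Y))
  out <- list(time = epochs$time, beta0 = as.numeric(B[1, ]),
              beta1 = as.numeric(B[2, ]), n = length(k),
              participant = epochs$participant, session = epochs$session)
  class(out) <- "error_regression"
  out
}

#' Locate the peak of a time course
#'
#' Time of the maximum within a search window (closed); ties break toward
#' the earliest time, and a peak on the window edge is flagged as a boundary
#' peak.
#'
#' @param tc A `timecourse`-like object (fields `time`, `values`) or any
#'   list with those fields (`mean` is used for `timewise_test` objects).
#' @param search_window `c(start, end)` in s; defaults to the full extent.
#' @return List: `time`, `value`, `index` (into `tc$time`), `boundary`.
#' @export
find_peak <- function(tc, search_window = range(tc$time)) {
  vals <- if (!is.null(tc$values)) tc$values else tc$mean
  stopifnot(length(vals) == length(tc$time), length(search_window) == 2)
  sel <- which(tc$time >= search_window[1] - 1e-9 &
                 tc$time <= search_window[2] + 1e-9)
  if (!length(sel)) stop("empty peak search window")
  i <- sel[which.max(vals[sel])]
  list(time = tc$time[i], value = vals[i], index = i,
       boundary = i == sel[1] || i == sel[length(sel)])
}

#' Mean of an individual time course around a peak
#'
#' Averages the samples whose time lies within `center +/- halfwidth`
#' (closed interval); at 60 Hz a halfwidth of 0.25 s covers 31 samples and
#' 0.05 s covers 7. A window reaching outside the analysis interval is an
#' error, never silently clipped.
#'
#' @param tc A `timecourse`-like object.
#' @param center Window center (s), typically a group-level peak time.
#' @param halfwidth Half-width (s), e.g. 0.25 or 0.05.
#' @return List of class `peak_window_scalar`: `center`, `halfwidth`,
#'   `value`, `n_samples`, `participant`, `session`.
#' @export
window_mean <- function(tc, center, halfwidth) {
  vals <- if (!is.null(tc$values)) tc$values else tc$mean
  stopifnot(halfwidth > 0)
  tol <- 1e-9
  if (center - halfwidth < min(tc$time) - tol ||
      center + halfwidth > max(tc$time) + tol) {
    stop("peak window extends outside the analysis interval")
  }
  sel <- abs(tc$time - center) <= halfwidth + tol
  out <- list(center = center, halfwidth = halfwidth,
              value = mean(vals[sel]), n_samples = sum(sel),
              participant = tc$participant, session = tc$session)
  class(out) <- "peak_window_scalar"
  out
}
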