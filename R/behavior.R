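#' Compute per-trial timing errors and clamped feedback values
#'
#' Fills the derived columns of a trial table: signed error `rt - target`,
#' absolute error, and the feedback value actually displayed, which is the
#' RT mapped onto the bounded feedback scale (intervals outside the range
#' are mapped to the boundaries, boundaries inclusive). Missing RTs
#' propagate as missing; nonpositive RTs are flagged invalid and reported.
#' The operation is idempotent: all derived columns are recomputed from `rt`.
#'
#' @param trials Data frame with at least an `rt` column (ms); `trial_index`
#'   and `block` are added if absent.
#' @param target Target interval (ms).
#' @param feedback_range Bounds of the feedback scale (ms).
#'
#' @return `trials` with columns `signed_error`, `abs_error`,
#'   `feedback_value` and logical `valid`; invalid row indices are attached
#'   as attribute `invalid_rows`.
#' @export
compute_errors <- function(trials, target = 1200,
                           feedback_range = c(600, 1800)) {
  stopifnot(is.data.frame(trials), "rt" %in% names(trials), target > 0,
            feedback_range[1] < feedback_range[2])
  if (is.null(trials$trial_index)) trials$trial_index <- seq_len(nrow(trials))
  if (is.null(trials$block)) trials$block <- 1L
  rt <- trials$rt
  valid <- is.na(rt) | rt > 0
  trials$signed_error <- ifelse(valid, rt - target, NA_real_)
  trials$abs_error <- abs(trials$signed_error)
  trials$feedback_value <- ifelse(valid,
                                  pmin(feedback_range[2],
                                       pmax(feedback_range[1], rt)),
                                  NA_real_)
  trials$valid <- valid
  bad <- which(!valid)
  attr(trials, "invalid_rows") <- bad
  if (length(bad)) {
    warning(sprintf("%d trial(s) with nonpositive RT flagged invalid (rows %s)",
                    length(bad), paste(utils::head(bad, 5), collapse = ", ")))
  }
  trials
}

#' Per-session behavioral summary
#'
#' Mean response time and mean absolute deviation from the target interval,
#' computed over valid, non-missing trials only.
#'
#' @param trials A trial table from [compute_errors()].
#' @return One-row data frame: `n_trials`, `n_valid`, `mean_rt`,
#'   `mean_abs_error`.
#' @export
summarize_behavior <- function(trials) {
  stopifnot(is.data.frame(trials), all(c("rt", "abs_error") %in% names(trials)))
  ok <- !is.na(trials$rt) & (is.null(trials$valid) | trials$valid %in% TRUE)
  if (!any(ok)) stop("no valid trials to summarize")
  data.frame(n_trials = nrow(trials), n_valid = sum(ok),
             mean_rt = mean(trials$rt[ok]),
             mean_abs_error = mean(trials$abs_error[ok]))
}

#' Trial-to-trial adjustment regression
#'
#' Fits, by ordinary least squares, the sequential-adjustment model
#' `dRT[t] = b0 + b1 * RT[t-1] + b2 * RT[t-1] * |error|[t-1]`, where
#' `dRT[t] = RT[t] - RT[t-1]`. `b1` captures regression to the mean across
#' adjacent trials (strongly negative for weakly autocorrelated series);
#' `b2`, the adjustment coefficient, captures error-magnitude-driven change
#' over and above it — negative values mean participants sped up after
#' especially slow responses and slowed after fast ones. Consecutive-trial
#' pairs are formed within blocks only, and pairs containing a missing or
#' invalid RT are dropped listwise. Fitted in milliseconds, unstandardized,
#' so `b2` is numerically small (~1e-4 scale).
#'
#' @param trials A trial table from [compute_errors()] (columns `rt`,
#'   `abs_error`, `block`, `trial_index`).
#' @param min_pairs Minimum number of usable pairs; fewer is an error.
#'
#' @return An object of class `adjustment_fit`: coefficients `beta0` (ms),
#'   `beta1` (unitless), `beta2` (1/ms), their standard errors, `n_pairs`,
#'   residual SD `sigma` and `df_residual`.
#' @export
fit_adjustment_model <- function(trials, min_pairs = 10) {
  stopifnot(is.data.frame(trials),
            all(c("rt", "abs_error", "block", "trial_index") %in% names(trials)))
  o <- order(trials$block, trials$trial_index)
  tr <- trials[o, ]
  ok <- !is.na(tr$rt) & tr$rt > 0
  i_cur <- which(c(FALSE, diff(tr$trial_index) == 1 & diff(tr$block) == 0))
  i_prev <- i_cur - 1L
  use <- ok[i_cur] & ok[i_prev]
  i_cur <- i_cur[use]; i_prev <- i_prev[use]
  n <- length(i_cur)
  if (n < min_pairs) {
    stop(sprintf("only %d usable consecutive-trial pairs (minimum %d)",
                 n, min_pairs))
  }
  y <- tr$rt[i_cur] - tr$rt[i_prev]
  x1 <- tr$rt[i_prev]
  x2 <- tr$rt[i_prev] * tr$abs_error[i_prev]
  X <- cbind(`(Intercept)` = 1, rt_prev = x1, rt_x_abs_err = x2)
  if (qr(X)$rank < 3L) {
    stop("degenerate design: regressors [1, RT[t-1], RT[t-1]*|error|[t-1]] ",
         "are rank-deficient (e.g. constant RT series)")
  }
  fit <- stats::lm.fit(X, y)
  res <- fit$residuals
  dfres <- n - 3L
  sigma2 <- sum(res^2) / dfres
  R <- qr.R(fit$qr)
  xtx_inv <- chol2inv(R)[order(fit$qr$pivot), order(fit$qr$pivot)]
  se <- sqrt(diag(xtx_inv) * sigma2)
  coefs <- fit$coefficients
  if (any(!is.finite(coefs))) stop("non-finite coefficients in adjustment fit")
  out <- list(beta0 = unname(coefs[1]), beta1 = unname(coefs[2]),
              beta2 = unname(coefs[3]),
              se0 = unname(se[1]), se1 = unname(se[2]), se2 = unname(se[3]),
              n_pairs = n, sigma = sqrt(sigma2), df_residual = dfres)
  class(out) <- "adjustment_fit"
  out
}

#' @export
print.adjustment_fit <- function(x, ...) {
  cat("Trial-to-trial adjustment model (OLS on", x$n_pairs, "pairs)\n")
  cat(sprintf("  b0 (intercept)     %10.3f ms  (SE %.3f)\n", x$beta0, x$se0))
  cat(sprintf("  b1 (lag RT)        %10.4f     (SE %.4f)\n", x$beta1, x$se1))
  cat(sprintf("  b2 (adjustment)    %10.3e /ms (SE %.2e)\n", x$beta2, x$se2))
  invisible(x)
}
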