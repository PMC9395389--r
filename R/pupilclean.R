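#' Select the eye with the larger proportion of high-quality samples
#'
#' @param samples Samples table with `conf_left` and `conf_right` columns.
#' @param conf_threshold Confidence threshold; samples at or above it count
#'   as high quality.
#' @return `"left"` or `"right"`; exact ties break to `"left"`. If both eyes
#'   are entirely below threshold a warning is issued and `"left"` is
#'   returned (downstream rejection handles quality).
#' @export
select_eye <- function(samples, conf_threshold = 0.6) {
  stopifnot(all(c("conf_left", "conf_right") %in% names(samples)),
            nrow(samples) > 0)
  frac_l <- mean(samples$conf_left >= conf_threshold)
  frac_r <- mean(samples$conf_right >= conf_threshold)
  if (frac_l == 0 && frac_r == 0) {
    warning("both eyes entirely below the confidence threshold; using left")
    return("left")
  }
  if (frac_r > frac_l) "right" else "left"
}

#' Detect artefactual samples by confidence and derivative criteria
#'
#' A sample is flagged if its confidence is below `conf_threshold` or the
#' absolute first difference of the signal into it exceeds `deriv_sd` times
#' the SD of first differences. The difference SD is computed per block,
#' in a single pass, over differences between pairs of samples neither of
#' which is confidence-flagged. Adjacent flagged samples are merged into
#' intervals.
#'
#' @param trace Data frame with columns `t` (s), `value`, `conf`, `block`.
#' @param conf_threshold Confidence threshold (flag when below).
#' @param deriv_sd Derivative criterion in SDs of the first difference.
#' @param fs Sampling rate (Hz), used for interval durations.
#'
#' @return List with `mask` (logical per sample), `intervals` (data frame:
#'   `block`, `start`, `end` sample indices, `t_start`, `t_end` in s,
#'   `duration` in s), and `unusable_blocks` (blocks with every sample
#'   flagged).
#' @export
detect_artifacts <- function(trace, conf_threshold = 0.6, deriv_sd = 4,
                             fs = 60) {
  stopifnot(is.data.frame(trace),
            all(c("t", "value", "conf", "block") %in% names(trace)))
  n <- nrow(trace)
  mask <- logical(n)
  unusable <- c()
  for (b in unique(trace$block)) {
    idx <- which(trace$block == b)
    if (length(idx) < 3) {
      stop("block ", b, " has fewer than 3 samples")
    }
    v <- trace$value[idx]
    conf_flag <- trace$conf[idx] < conf_threshold
    d <- c(NA_real_, diff(v))
    # differences touching a confidence-flagged sample are excluded from SD
    clean_pair <- !conf_flag & !c(TRUE, conf_flag[-length(conf_flag)])
    sdd <- stats::sd(d[clean_pair & !is.na(d)])
    deriv_flag <- !is.na(d) & !is.na(sdd) & sdd > 0 & abs(d) > deriv_sd * sdd
    m <- conf_flag | deriv_flag
    if (all(m)) unusable <- c(unusable, b)
    mask[idx] <- m
  }
  list(mask = mask, intervals = mask_intervals(mask, trace, fs),
       unusable_blocks = unusable)
}

mask_intervals <- function(mask, trace, fs = 60) {
  out <- data.frame(block = integer(0), start = integer(0), end = integer(0),
                    t_start = numeric(0), t_end = numeric(0),
                    duration = numeric(0))
  for (b in unique(trace$block)) {
    idx <- which(trace$block == b)
    r <- rle(mask[idx])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- which(r$values)
    if (!length(keep)) next
    s <- idx[starts[keep]]; e <- idx[ends[keep]]
    out <- rbind(out, data.frame(block = b, start = s, end = e,
                                 t_start = trace$t[s], t_end = trace$t[e],
                                 duration = (e - s + 1L) / fs))
  }
  out
}

#' Linearly interpolate over artefactual samples
#'
#' Flagged interior samples are replaced by linear interpolation between the
#' nearest unflagged neighbors within the same block; leading or trailing
#' flagged runs are filled by nearest-value extension (no extrapolation).
#'
#' @param trace Data frame with columns `t`, `value`, `block`.
#' @param mask Logical mask from [detect_artifacts()].
#' @return The trace values with gaps filled (numeric vector).
#' @export
interpolate_artifacts <- function(trace, mask) {
  stopifnot(nrow(trace) == length(mask))
  value <- trace$value
  for (b in unique(trace$block)) {
    idx <- which(trace$block == b)
    m <- mask[idx]
    if (!any(m)) next
    good <- which(!m)
    if (length(good) == 0) {
      stop("block ", b, " has no clean samples to interpolate from")
    }
    if (length(good) == 1) {
      value[idx] <- value[idx][good]
      next
    }
    value[idx] <- stats::approx(x = trace$t[idx][good],
                                y = value[idx][good],
                                xout = trace$t[idx], rule = 2)$y
  }
  value
}

# Steady-state-initialized IIR filter pass: equivalent to initializing the
# filter state so that a constant input yields its steady-state output
# immediately (no start-up transient for the DC component).
filter_ss <- function(b, a, x) {
  dc <- sum(b) / sum(a)
  as.numeric(signal::filter(b, a, x - x[1])) + x[1] * dc
}

# Zero-phase (forward-backward) IIR application with odd-reflection padding,
# so that low-cutoff high-pass filters do not ring at block edges.
filtfilt_ss <- function(b, a, x, padlen = 180L) {
  n <- length(x)
  padlen <- max(1L, min(padlen, n - 1L))
  ext <- c(2 * x[1] - x[(padlen + 1L):2],
           x,
           2 * x[n] - x[(n - 1L):(n - padlen)])
  y <- filter_ss(b, a, ext)
  y <- rev(filter_ss(b, a, rev(y)))
  y[(padlen + 1L):(padlen + n)]
}

#' Zero-phase Butterworth band-pass filtering
#'
#' Applies a 3rd-order Butterworth high-pass (default 0.06 Hz) followed by a
#' 3rd-order low-pass (default 6 Hz), each forward and backward so the net
#' filter has zero phase (event latencies are preserved) and the squared
#' single-pass magnitude response. Input must be gap-free (interpolated).
#'
#' @param x Numeric vector (one block of samples).
#' @param fs Sampling rate (Hz).
#' @param hp,lp High-/low-pass cutoffs (Hz); `lp` must be below `fs/2`.
#' @param order Butterworth order per pass.
#' @return Filtered vector of the same length.
#' @export
bandpass_filter <- function(x, fs = 60, hp = 0.06, lp = 6, order = 3) {
  stopifnot(is.numeric(x), fs > 0, hp > 0, lp > hp)
  if (lp >= fs / 2) stop("low-pass cutoff must be below the Nyquist frequency")
  min_len <- 9L * (order + 1L)  # settling guard: 3x the edge-transient span
  if (length(x) <= min_len) {
    stop(sprintf("block too short for stable filtering (%d samples, need > %d)",
                 length(x), min_len))
  }
  bf_h <- signal::butter(order, hp / (fs / 2), type = "high")
  bf_l <- signal::butter(order, lp / (fs / 2), type = "low")
  padlen <- min(length(x) - 1L, 3L * as.integer(fs))
  y <- filtfilt_ss(bf_h$b, bf_h$a, x, padlen)
  filtfilt_ss(bf_l$b, bf_l$a, y, padlen)
}

#' Normalize a filtered trace to percent of the per-block median
#'
#' The reference median is computed per block on the interpolated,
#' *pre-filter* samples (artifact spikes would otherwise bias it), and each
#' filtered sample is expressed as `100 * value / median(block)`.
#'
#' @param filtered Filtered values.
#' @param prefilter Interpolated, unfiltered values (same length).
#' @param block Block id per sample.
#' @return Normalized values with attribute `medians` (named per block).
#' @export
normalize_to_median <- function(filtered, prefilter, block) {
  stopifnot(length(filtered) == length(prefilter),
            length(filtered) == length(block))
  meds <- tapply(prefilter, block, stats::median)
  if (any(meds <= 0)) {
    stop("nonpositive per-block median: physically invalid recording")
  }
  out <- 100 * filtered / as.numeric(meds[as.character(block)])
  attr(out, "medians") <- meds
  out
}

#' Full pupil preprocessing: raw binocular stream to clean trace
#'
#' Composition of [select_eye()], [detect_artifacts()],
#' [interpolate_artifacts()], [bandpass_filter()] and
#' [normalize_to_median()], applied per block. Blocks in which every sample
#' is artefactual, or that are too short to filter, are marked unusable and
#' dropped from the output (recorded in the QC report).
#'
#' @param samples Samples table (`t`, `diam_left`, `conf_left`, `diam_right`,
#'   `conf_right`, `block`).
#' @param conf_threshold,deriv_sd Artifact criteria, see
#'   [detect_artifacts()].
#' @param fs,hp,lp,order Filter settings, see [bandpass_filter()].
#' @param long_interval_s Threshold used only for QC reporting of long
#'   artifact intervals (s).
#'
#' @return A `clean_trace` data frame: `t`, `value` (% of block median,
#'   high-pass filtered so it fluctuates around 0), `artifact_mask`,
#'   `block`; attributes `eye`, `intervals` (artifact intervals), `qc`
#'   (per-block report: n, fraction flagged, long intervals, usable,
#'   median), `medians`.
#' @export
preprocess_pupil <- function(samples, conf_threshold = 0.6, deriv_sd = 4,
                             fs = 60, hp = 0.06, lp = 6, order = 3,
                             long_interval_s = 0.75) {
  eye <- select_eye(samples, conf_threshold)
  trace <- data.frame(t = samples$t,
                      value = samples[[paste0("diam_", eye)]],
                      conf = samples[[paste0("conf_", eye)]],
                      block = samples$block)
  det <- detect_artifacts(trace, conf_threshold, deriv_sd, fs)

  blocks <- unique(trace$block)
  usable <- setdiff(blocks, det$unusable_blocks)
  prefilter <- trace$value
  filtered <- rep(NA_real_, nrow(trace))
  for (b in usable) {
    idx <- which(trace$block == b)
    prefilter[idx] <- interpolate_artifacts(trace[idx, , drop = FALSE],
                                            det$mask[idx])
    filt_b <- tryCatch(
      bandpass_filter(prefilter[idx], fs = fs, hp = hp, lp = lp,
                      order = order),
      error = function(e) {
        if (grepl("block too short", conditionMessage(e))) NULL else stop(e)
      })
    if (is.null(filt_b)) {
      usable <- setdiff(usable, b)
      next
    }
    filtered[idx] <- filt_b
  }
  if (!length(usable)) stop("no usable blocks after preprocessing")
  keep <- trace$block %in% usable
  norm <- normalize_to_median(filtered[keep], prefilter[keep],
                              trace$block[keep])
  qc <- do.call(rbind, lapply(blocks, function(b) {
    idx <- which(trace$block == b)
    iv <- det$intervals[det$intervals$block == b, , drop = FALSE]
    data.frame(block = b, n = length(idx),
               frac_flagged = mean(det$mask[idx]),
               n_long_intervals = sum(iv$duration > long_interval_s),
               usable = b %in% usable,
               median = if (b %in% usable)
                 as.numeric(attr(norm, "medians")[as.character(b)])
               else NA_real_)
  }))
  out <- data.frame(t = trace$t[keep], value = as.numeric(norm),
                    artifact_mask = det$mask[keep], block = trace$block[keep])
  class(out) <- c("clean_trace", "data.frame")
  attr(out, "eye") <- eye
  attr(out, "intervals") <- det$intervals[det$intervals$block %in% usable, ,
                                          drop = FALSE]
  attr(out, "qc") <- qc
  attr(out, "medians") <- attr(norm, "medians")
  out
}
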