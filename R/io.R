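#' Read a pupil samples file
#'
#' Delimited text with header columns `timestamp_s`, `diam_left`,
#' `conf_left`, `diam_right`, `conf_right`, `block` (any column order).
#' Validates confidences in \[0, 1\], strictly increasing timestamps and
#' nominal within-block sample spacing (tolerance 10%); malformed rows are
#' reported with their file line numbers.
#'
#' @param path File path.
#' @param fs Nominal sampling rate (Hz).
#' @return Data frame with internal column names: `t`, `diam_left`,
#'   `conf_left`, `diam_right`, `conf_right`, `block`.
#' @export
read_samples <- function(path, fs = 60) {
  req <- c("timestamp_s", "diam_left", "conf_left", "diam_right",
           "conf_right", "block")
  df <- as.data.frame(data.table::fread(path))
  miss <- setdiff(req, names(df))
  if (length(miss)) {
    stop("missing required column(s) in ", path, ": ",
         paste(miss, collapse = ", "))
  }
  df <- df[req]
  names(df)[1] <- "t"
  for (cc in c("conf_left", "conf_right")) {
    bad <- which(is.na(df[[cc]]) | df[[cc]] < 0 | df[[cc]] > 1)
    if (length(bad)) {
      stop(sprintf("%s: %s outside [0, 1] at line(s) %s", path, cc,
                   paste(utils::head(bad + 1L, 5), collapse = ", ")))
    }
  }
  dt <- diff(df$t)
  if (any(dt <= 0)) {
    stop(sprintf("%s: timestamps not strictly increasing at line %d",
                 path, which(dt <= 0)[1] + 2L))
  }
  same_block <- diff(df$block) == 0
  off <- which(same_block & abs(dt - 1 / fs) > 0.1 / fs)
  if (length(off)) {
    stop(sprintf("%s: sample spacing deviates >10%% from 1/%g s at line %d",
                 path, fs, off[1] + 2L))
  }
  df
}

#' Read a trial events file
#'
#' Delimited text with header columns `trial`, `block`, `stim_onset_ms`,
#' `rt_ms` (any column order). Onsets must be strictly increasing; RTs must
#' be positive or empty (missing).
#'
#' @param path File path.
#' @return Data frame with internal names `trial_index`, `block`,
#'   `stim_onset`, `rt`.
#' @export
read_trials <- function(path) {
  req <- c("trial", "block", "stim_onset_ms", "rt_ms")
  df <- as.data.frame(data.table::fread(path))
  miss <- setdiff(req, names(df))
  if (length(miss)) {
    stop("missing required column(s) in ", path, ": ",
         paste(miss, collapse = ", "))
  }
  df <- df[req]
  names(df) <- c("trial_index", "block", "stim_onset", "rt")
  if (any(diff(df$stim_onset) <= 0)) {
    stop(path, ": stimulus onsets are not strictly increasing")
  }
  bad <- which(!is.na(df$rt) & df$rt <= 0)
  if (length(bad)) {
    stop(sprintf("%s: nonpositive RT at line(s) %s", path,
                 paste(utils::head(bad + 1L, 5), collapse = ", ")))
  }
  df
}

#' Write a samples table
#'
#' Inverse of [read_samples()] (columns are written under the file schema
#' names).
#'
#' @param samples Samples table (internal names).
#' @param path Destination.
#' @return `path`, invisibly.
#' @export
write_samples <- function(samples, path) {
  out <- data.frame(timestamp_s = samples$t,
                    diam_left = samples$diam_left,
                    conf_left = samples$conf_left,
                    diam_right = samples$diam_right,
                    conf_right = samples$conf_right,
                    block = samples$block)
  data.table::fwrite(out, path)
  invisible(path)
}

#' Write a trial table
#'
#' Inverse of [read_trials()]; only the raw event columns are written
#' (derived error columns are recomputed on read).
#'
#' @param trials Trial table (internal names).
#' @param path Destination.
#' @return `path`, invisibly.
#' @export
write_trials <- function(trials, path) {
  out <- data.frame(trial = trials$trial_index, block = trials$block,
                    stim_onset_ms = trials$stim_onset, rt_ms = trials$rt)
  data.table::fwrite(out, path)
  invisible(path)
}
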