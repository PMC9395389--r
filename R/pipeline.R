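#' Pipeline configuration
#'
#' Collects every constant of the analysis with the task's standard values
#' as defaults: 1200-ms target, 600--1800 ms feedback clamp, 2000-ms trial
#' timeout, confidence threshold 0.6, 4-SD derivative criterion, 0.06/6 Hz
#' 3rd-order zero-phase Butterworth filtering, task segmentation
#' \[-1500, 1000\] ms (pre-stimulus baseline \[-400, 0\]) and feedback
#' segmentation \[0, 1500\] ms (pre-response baseline), rejection rules
#' (RT < 400 ms, > 50% artefactual samples, overlap with > 750 ms artifact),
#' peak-window halfwidths 250 and 50 ms, alpha 0.05.
#'
#' @param input Directory holding (or to hold) the dataset.
#' @param output Directory for the results bundle.
#' @param simulate If `TRUE`, simulate a cohort into `input` first.
#' @param spec [cohort_spec()] used when simulating.
#' @param truth [sim_truth()] used when simulating.
#' @param seed Integer seed for the whole run.
#' @param overwrite Allow writing into non-empty directories.
#' @param target,feedback_range,trial_timeout Task constants (ms).
#' @param conf_threshold,deriv_sd,fs,hp,lp,order Preprocessing constants.
#' @param rt_min,max_artifact_frac,long_artifact_ms Rejection constants.
#' @param halfwidths Peak-window halfwidths (s).
#' @param alpha Pointwise significance level.
#' @param p_adjust_method Adjustment for the per-cell one-sample tests.
#' @return An object of class `run_config`.
#' @export
run_config <- function(input, output, simulate = FALSE,
                       spec = cohort_spec(), truth = sim_truth(),
                       seed = 1L, overwrite = FALSE,
                       target = 1200, feedback_range = c(600, 1800),
                       trial_timeout = 2000,
                       conf_threshold = 0.6, deriv_sd = 4, fs = 60,
                       hp = 0.06, lp = 6, order = 3,
                       rt_min = 400, max_artifact_frac = 0.5,
                       long_artifact_ms = 750,
                       halfwidths = c(0.25, 0.05), alpha = 0.05,
                       p_adjust_method = "holm") {
  stopifnot(target > 0, trial_timeout > 0, conf_threshold > 0,
            conf_threshold <= 1, deriv_sd > 0, fs > 0, hp > 0, lp > hp,
            order >= 1, rt_min > 0, max_artifact_frac > 0,
            max_artifact_frac < 1, long_artifact_ms > 0,
            all(halfwidths > 0), alpha > 0, alpha < 1)
  if (lp >= fs / 2) stop("low-pass cutoff must be below Nyquist (fs/2)")
  cfg <- list(input = input, output = output, simulate = simulate,
              spec = spec, truth = truth, seed = as.integer(seed),
              overwrite = overwrite, target = target,
              feedback_range = feedback_range,
              trial_timeout = trial_timeout,
              conf_threshold = conf_threshold, deriv_sd = deriv_sd,
              fs = fs, hp = hp, lp = lp, order = order, rt_min = rt_min,
              max_artifact_frac = max_artifact_frac,
              long_artifact_ms = long_artifact_ms,
              halfwidths = halfwidths, alpha = alpha,
              p_adjust_method = p_adjust_method)
  class(cfg) <- "run_config"
  cfg
}

#' Hash a configuration for provenance
#'
#' MD5 of the canonical JSON serialization of all analysis constants
#' (paths excluded); changing any constant changes the hash.
#'
#' @param config A [run_config()].
#' @return Hex string.
#' @export
config_hash <- function(config) {
  x <- unclass(config)
  x$input <- NULL; x$output <- NULL; x$overwrite <- NULL
  x$spec <- unclass(x$spec); x$truth <- unclass(x$truth)
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(x, tmp, auto_unbox = TRUE, digits = NA,
                       null = "null")
  unname(tools::md5sum(tmp))
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate (optional) -> read -> behavioral scoring ->
#' pupil preprocessing -> epoching and rejection -> time-resolved statistics
#' -> group inference, and writes the results bundle: behavior summaries and
#' peak-window scalars (CSV), per-participant time courses (CSV), group
#' statistics (JSON), a QC report (CSV), a manifest carrying the config hash
#' and seed, and a plain-text log. The bundle is deterministic given
#' (dataset, config, seed): the log and manifest contain no timestamps.
#'
#' @param config A [run_config()].
#' @return Invisibly, the in-memory results list.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  log_lines <- character(0)
  logf <- function(...) {
    line <- sprintf(...)
    log_lines <<- c(log_lines, line)
    invisible(line)
  }
  stage <- "setup"
  res <- tryCatch(
    run_pipeline_stages(config, logf),
    error = function(e) {
      stop(sprintf("pipeline failed in stage [%s]: %s",
                   attr(e, "stage") %||% "unknown", conditionMessage(e)),
           call. = FALSE)
    })
  dir.create(config$output, showWarnings = FALSE, recursive = TRUE)
  out <- config$output
  data.table::fwrite(res$behavior, file.path(out, "behavior_summaries.csv"))
  data.table::fwrite(res$scalars, file.path(out, "peak_scalars.csv"))
  data.table::fwrite(res$qc, file.path(out, "qc.csv"))
  data.table::fwrite(res$timecourses, file.path(out, "timecourses.csv"))
  jsonlite::write_json(res$stats, file.path(out, "group_stats.json"),
                       auto_unbox = TRUE, digits = 10, null = "null",
                       na = "null")
  manifest <- list(package = "pupiltiming",
                   version = as.character(utils::packageVersion("pupiltiming")),
                   seed = config$seed, config_hash = config_hash(config),
                   n_participant_sessions = nrow(res$qc))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  writeLines(c(res$log, log_lines), file.path(out, "log.txt"))
  invisible(res)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    attr(e, "stage") <- stage
    stop(e)
  })
}

run_pipeline_stages <- function(config, logf) {
  set.seed(config$seed)
  logf("pipeline start (seed %d, config %s)", config$seed,
       config_hash(config))

  with_stage("simulate", {
    if (config$simulate) {
      simulate_cohort(config$spec, config$truth, config$input,
                      seed = config$seed, overwrite = config$overwrite)
      logf("simulated cohort into %s", config$input)
    }
  })

  meta <- with_stage("read", {
    if (!file.exists(file.path(config$input, "participants.csv"))) {
      stop("no participants.csv in ", config$input)
    }
    as.data.frame(data.table::fread(file.path(config$input,
                                              "participants.csv")))
  })
  sessions <- config$spec$sessions

  behavior <- list(); scalars <- list(); qc <- list()
  task_tcs <- list(); fb_tcs <- list(); breg <- list()
  tc_rows <- list()

  for (i in seq_len(nrow(meta))) {
    for (s in sessions) {
      id <- sprintf("%s_s%s", meta$participant[i], s)
      trials <- with_stage("behavior", {
        tr <- read_trials(file.path(config$input,
                                    sprintf("trials_%s.csv", id)))
        compute_errors(tr, target = config$target,
                       feedback_range = config$feedback_range)
      })
      beh <- with_stage("behavior", {
        sm <- summarize_behavior(trials)
        fit <- tryCatch(fit_adjustment_model(trials),
                        error = function(e) NULL)
        cbind(data.frame(participant = meta$participant[i],
                         group = meta$group[i], session = s), sm,
              data.frame(beta0 = fit$beta0 %||% NA_real_,
                         beta1 = fit$beta1 %||% NA_real_,
                         beta2 = fit$beta2 %||% NA_real_,
                         se2 = fit$se2 %||% NA_real_,
                         n_pairs = fit$n_pairs %||% NA_integer_))
      })
      behavior[[id]] <- beh

      spath <- file.path(config$input, sprintf("samples_%s.csv", id))
      if (!file.exists(spath)) next
      trace <- with_stage("preprocess", {
        smp <- read_samples(spath, fs = config$fs)
        preprocess_pupil(smp, conf_threshold = config$conf_threshold,
                         deriv_sd = config$deriv_sd, fs = config$fs,
                         hp = config$hp, lp = config$lp,
                         order = config$order,
                         long_interval_s = config$long_artifact_ms / 1000)
      })
      iv <- attr(trace, "intervals")
      eps <- with_stage("epoch", {
        lapply(list(task = task_epoch_spec(), fb = feedback_epoch_spec()),
               function(es) {
                 ep <- extract_epochs(trace, trials, es, fs = config$fs)
                 ep$participant <- meta$participant[i]
                 ep$session <- s
                 reject_trials(ep, iv, rt_min = config$rt_min,
                               max_artifact_frac = config$max_artifact_frac,
                               long_artifact_ms = config$long_artifact_ms)
               })
      })
      qcb <- attr(trace, "qc")
      qc[[id]] <- data.frame(
        participant = meta$participant[i], session = s,
        eye = attr(trace, "eye"),
        n_blocks_usable = sum(qcb$usable),
        frac_flagged = stats::weighted.mean(qcb$frac_flagged, qcb$n),
        n_long_intervals = sum(qcb$n_long_intervals),
        task_kept = sum(eps$task$kept), fb_kept = sum(eps$fb$kept),
        task_rejected = paste(names(table(eps$task$reason[!eps$task$kept])),
                              table(eps$task$reason[!eps$task$kept]),
                              sep = ":", collapse = ";"))
      tca <- suppressWarnings(average_epochs(eps$task))
      fba <- suppressWarnings(average_epochs(eps$fb))
      br <- suppressWarnings(timewise_error_regression(eps$fb))
      if (is.null(tca) || is.null(fba) || is.null(br)) {
        logf("dropping %s listwise (no usable epochs)", id)
        next
      }
      task_tcs[[id]] <- tca; fb_tcs[[id]] <- fba; breg[[id]] <- br
      tc_rows[[id]] <- rbind(
        data.frame(participant = meta$participant[i], session = s,
                   kind = "task_mean", time = tca$time, value = tca$values),
        data.frame(participant = meta$participant[i], session = s,
                   kind = "fb_mean", time = fba$time, value = fba$values),
        data.frame(participant = meta$participant[i], session = s,
                   kind = "fb_beta1", time = br$time, value = br$beta1))
    }
  }
  behavior <- do.call(rbind, behavior)
  rownames(behavior) <- NULL
  have_pupil <- length(task_tcs) > 0

  stats_out <- list()
  scalar_rows <- list()
  if (have_pupil) {
    with_stage("timecourse_stats", {
      tw <- timewise_one_sample(task_tcs, alpha = config$alpha)
      grand_task <- timecourse(tw$time, tw$mean, "mean", tw$n)
      task_peak <- find_peak(grand_task)
      logf("task-related pupil response peaks %.3f s after the response",
           task_peak$time)
      beta1_mat <- do.call(rbind, lapply(breg, function(b) b$beta1))
      grand_b1 <- timecourse(breg[[1]]$time, colMeans(beta1_mat), "beta")
      b1_peak <- find_peak(grand_b1, c(0, 1.5))
      stats_out$task_timewise <- list(
        peak_time = task_peak$time, peak_value = task_peak$value,
        peak_on_boundary = task_peak$boundary,
        sig_interval = as.list(tw$sig_interval), n = tw$n)
      stats_out$fb_regression <- list(
        peak_time = b1_peak$time, peak_value = b1_peak$value,
        peak_on_boundary = b1_peak$boundary, n = nrow(beta1_mat))
      # a peak on the interval edge cannot carry a full +/-hw window;
      # shift the center inward just enough and log the adjustment
      fit_center <- function(center, hw, time) {
        lo <- min(time) + hw; hi <- max(time) - hw
        adj <- min(max(center, lo), hi)
        if (abs(adj - center) > 1e-9) {
          logf("peak window center moved from %.3f to %.3f s to fit the %s",
               center, adj, "analysis interval")
        }
        adj
      }
      for (hw in config$halfwidths) {
        lab <- sprintf("%dms", round(hw * 1000))
        c_task <- fit_center(task_peak$time, hw, tw$time)
        c_fb <- fit_center(b1_peak$time, hw, breg[[1]]$time)
        for (id in names(task_tcs)) {
          pc <- task_tcs[[id]]
          scalar_rows[[paste("task", lab, id)]] <- data.frame(
            participant = pc$participant, session = pc$session,
            measure = paste0("task_dilation_", lab),
            center = c_task, halfwidth = hw,
            value = window_mean(pc, c_task, hw)$value)
          fc <- fb_tcs[[id]]
          scalar_rows[[paste("fb", lab, id)]] <- data.frame(
            participant = fc$participant, session = fc$session,
            measure = paste0("fb_dilation_", lab),
            center = c_fb, halfwidth = hw,
            value = window_mean(fc, c_fb, hw)$value)
          bc <- breg[[id]]
          scalar_rows[[paste("b1", lab, id)]] <- data.frame(
            participant = bc$participant, session = bc$session,
            measure = paste0("fb_beta1_", lab),
            center = c_fb, halfwidth = hw,
            value = window_mean(list(time = bc$time, values = bc$beta1,
                                     participant = bc$participant,
                                     session = bc$session),
                                c_fb, hw)$value)
        }
      }
    })
  }
  scalars <- if (length(scalar_rows)) do.call(rbind, scalar_rows) else
    data.frame(participant = character(0), session = character(0),
               measure = character(0), center = numeric(0),
               halfwidth = numeric(0), value = numeric(0))
  rownames(scalars) <- NULL

  with_stage("inference", {
    grp <- meta$group[match(behavior$participant, meta$participant)]
    mk_cell <- function(value) data.frame(
      participant = behavior$participant, group = grp,
      session = behavior$session, value = value)
    anova_safe <- function(cd) tryCatch({
      a <- mixed_anova_2x2(cd)
      list(table = a$table, shapiro_p = a$shapiro_p)
    }, error = function(e) list(error = conditionMessage(e)))
    stats_out$anova <- list(
      mean_rt = anova_safe(mk_cell(behavior$mean_rt)),
      mean_abs_error = anova_safe(mk_cell(behavior$mean_abs_error)),
      adjustment_beta2 = anova_safe(mk_cell(behavior$beta2)))
    stats_out$adjustment_one_sample <- tryCatch(
      adjusted_one_sample_tests(mk_cell(behavior$beta2),
                                method = config$p_adjust_method),
      error = function(e) list(error = conditionMessage(e)))
    # non-parametric fallback: session-2-minus-session-1 change per
    # participant, compared between groups
    wide <- stats::reshape(
      behavior[c("participant", "session", "mean_abs_error")],
      idvar = "participant", timevar = "session", direction = "wide")
    if (ncol(wide) == 3) {
      chg <- wide[[3]] - wide[[2]]
      g <- meta$group[match(wide$participant, meta$participant)]
      gs <- sort(unique(g))
      stats_out$abs_error_session_change_mw <- tryCatch(
        rank_tests(chg[g == gs[2]], chg[g == gs[1]], mode = "unpaired"),
        error = function(e) list(error = conditionMessage(e)))
    }
    if (have_pupil) {
      for (ms in unique(scalars$measure)) {
        sc <- scalars[scalars$measure == ms, ]
        cd <- data.frame(participant = sc$participant,
                         group = meta$group[match(sc$participant,
                                                  meta$participant)],
                         session = sc$session, value = sc$value)
        stats_out$anova[[ms]] <- anova_safe(cd)
      }
    }
    if ("dose_mg_per_kg" %in% names(meta) &&
        any(!is.na(meta$dose_mg_per_kg)) && ncol(wide) == 3) {
      pat <- meta$participant[!is.na(meta$dose_mg_per_kg)]
      sel <- wide$participant %in% pat
      dose <- meta$dose_mg_per_kg[match(wide$participant[sel],
                                        meta$participant)]
      stats_out$dose_correlations <- list(
        abs_error_change = tryCatch(
          pearson_corr((wide[[3]] - wide[[2]])[sel], dose),
          error = function(e) list(error = conditionMessage(e))))
    }
  })

  qc <- if (length(qc)) do.call(rbind, qc) else
    data.frame(participant = behavior$participant,
               session = behavior$session)
  rownames(qc) <- NULL
  timecourses <- if (length(tc_rows)) do.call(rbind, tc_rows) else
    data.frame(participant = character(0), session = character(0),
               kind = character(0), time = numeric(0), value = numeric(0))
  rownames(timecourses) <- NULL
  list(behavior = behavior, scalars = scalars, qc = qc,
       timecourses = timecourses, stats = stats_out,
       log = sprintf("analyzed %d participant-sessions (%d with pupil data)",
                     nrow(behavior), length(task_tcs)))
}
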