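#' Two-by-two mixed-design ANOVA with partial eta squared
#'
#' Classical mixed-model decomposition for one between-subject factor
#' (Group) and one within-subject factor (Session): the between-subject
#' error (subjects within groups) tests Group; the subject-by-session error
#' tests Session and the Group x Session interaction. Partial eta squared is
#' `SS_effect / (SS_effect + SS_error)` with each effect's own error term.
#' Participants missing a session are dropped listwise (logged via a
#' message); residual normality is summarized by a Shapiro-Wilk test on the
#' within-cell residuals.
#'
#' @param data Data frame with columns `participant`, `group`, `session`,
#'   `value` (at most one value per participant-session).
#' @return An object of class `anova_mixed`: a data frame `table` (effect,
#'   df_num, df_den, ss, ss_error, F, p, pes), `shapiro_p`, `n_per_group`,
#'   `dropped` (participants removed listwise).
#' @export
mixed_anova_2x2 <- function(data) {
  stopifnot(all(c("participant", "group", "session", "value") %in%
                  names(data)))
  d <- data[!is.na(data$value), ]
  d$participant <- as.character(d$participant)
  sessions <- sort(unique(as.character(d$session)))
  tab <- table(d$participant)
  complete <- names(tab)[tab == length(sessions)]
  dropped <- setdiff(unique(d$participant), complete)
  if (length(dropped)) {
    message("dropping incomplete participant(s): ",
            paste(dropped, collapse = ", "))
  }
  d <- d[d$participant %in% complete, ]
  if (any(duplicated(d[c("participant", "session")]))) {
    stop("more than one value per participant-session")
  }
  grp_of <- tapply(as.character(d$group), d$participant,
                   function(g) unique(g))
  if (any(lengths(grp_of) != 1)) {
    stop("a participant appears in more than one group")
  }
  n_per_group <- table(unlist(grp_of))
  if (length(n_per_group) != 2 || any(n_per_group < 2)) {
    stop("need 2 groups with at least 2 complete participants each")
  }
  d$participant <- factor(d$participant)
  d$group <- factor(as.character(d$group))
  d$session <- factor(as.character(d$session))
  fit <- stats::aov(value ~ group * session + Error(participant), data = d)
  sm <- summary(fit)
  btw <- as.data.frame(sm[["Error: participant"]][[1]])
  wth <- as.data.frame(sm[["Error: Within"]][[1]])
  rn_b <- trimws(rownames(btw)); rn_w <- trimws(rownames(wth))
  pick <- function(tabdf, rn, name) tabdf[match(name, rn), , drop = FALSE]
  eff <- function(name, tabdf, rn) {
    row <- pick(tabdf, rn, name)
    err <- pick(tabdf, rn, "Residuals")
    data.frame(effect = name, df_num = row$Df, df_den = err$Df,
               ss = row$`Sum Sq`, ss_error = err$`Sum Sq`,
               F = row$`F value`, p = row$`Pr(>F)`,
               pes = row$`Sum Sq` / (row$`Sum Sq` + err$`Sum Sq`))
  }
  table_out <- rbind(eff("group", btw, rn_b),
                     eff("session", wth, rn_w),
                     eff("group:session", wth, rn_w))
  table_out$effect <- c("group", "session", "interaction")
  # within-cell residuals: value - cell mean - (subject mean - group mean)
  cellm <- stats::ave(d$value, d$group, d$session)
  subjm <- stats::ave(d$value, d$participant)
  grpm <- stats::ave(d$value, d$group)
  resid_within <- d$value - cellm - (subjm - grpm)
  shapiro_p <- tryCatch(stats::shapiro.test(resid_within)$p.value,
                        error = function(e) NA_real_)
  out <- list(table = table_out, shapiro_p = shapiro_p,
              n_per_group = as.list(n_per_group), dropped = dropped)
  class(out) <- "anova_mixed"
  out
}

#' @export
print.anova_mixed <- function(x, ...) {
  cat("Mixed ANOVA (Group between, Session within)\n")
  for (i in seq_len(nrow(x$table))) {
    r <- x$table[i, ]
    cat(sprintf("  %-12s F(%d,%d) = %6.3f, p = %.4f, pes = %.3f\n",
                r$effect, r$df_num, r$df_den, r$F, r$p, r$pes))
  }
  cat(sprintf("  Shapiro-Wilk on residuals: p = %.4f\n", x$shapiro_p))
  invisible(x)
}

#' One-sample t-tests per group-by-session cell with adjusted p-values
#'
#' Tests whether the scores in each of the four cells deviate from zero
#' (two-sided) and adjusts the p-values across the four tests (Holm
#' step-down by default; the adjustment method is configurable).
#'
#' @param data Data frame with `group`, `session`, `value`.
#' @param mu Null value.
#' @param method Adjustment method passed to [stats::p.adjust()].
#' @return Data frame: `group`, `session`, `n`, `mean`, `t`, `df`, `p`,
#'   `p_adj`. Cells with zero variance get `NA` statistics (flagged by a
#'   warning) and are excluded from the adjustment.
#' @export
adjusted_one_sample_tests <- function(data, mu = 0, method = "holm") {
  stopifnot(all(c("group", "session", "value") %in% names(data)))
  cells <- unique(data[c("group", "session")])
  cells <- cells[order(cells$group, cells$session), ]
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    v <- data$value[data$group == cells$group[i] &
                      data$session == cells$session[i]]
    v <- v[!is.na(v)]
    if (length(v) < 3) stop("fewer than 3 values in cell ",
                            cells$group[i], "/", cells$session[i])
    if (stats::sd(v) == 0) {
      warning("zero variance in cell ", cells$group[i], "/",
              cells$session[i], ": test undefined")
      return(data.frame(group = cells$group[i], session = cells$session[i],
                        n = length(v), mean = mean(v), t = NA_real_,
                        df = length(v) - 1, p = NA_real_))
    }
    tt <- stats::t.test(v, mu = mu)
    data.frame(group = cells$group[i], session = cells$session[i],
               n = length(v), mean = mean(v),
               t = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- NA_real_
  ok <- !is.na(out$p)
  out$p_adj[ok] <- stats::p.adjust(out$p[ok], method = method)
  out
}

#' Rank tests: Mann-Whitney and Wilcoxon signed-rank
#'
#' Unpaired mode compares two independent samples (Mann-Whitney U); paired
#' mode tests the signed ranks of the pairwise differences, dropping zero
#' differences. The exact permutation null is enumerated for small samples
#' (n <= `exact_max_n` per group, no ties); otherwise the normal
#' approximation with continuity (and tie) correction is used.
#'
#' @param x,y Numeric vectors (equal length in paired mode).
#' @param mode `"unpaired"` or `"paired"`.
#' @param exact_max_n Largest per-group n for exact enumeration.
#' @return List: `statistic` (W), `p`, `method`, `exact`, `n`.
#' @export
rank_tests <- function(x, y, mode = c("unpaired", "paired"),
                       exact_max_n = 12) {
  mode <- match.arg(mode)
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  paired <- mode == "paired"
  if (paired) {
    if (length(x) != length(y)) stop("paired mode needs equal lengths")
    dif <- x - y
    dif <- dif[dif != 0]
    if (!length(dif)) stop("all paired differences are zero")
    ties <- any(duplicated(abs(dif))) || length(dif) < length(x)
    n_eff <- length(dif)
  } else {
    ties <- any(duplicated(c(x, y)))
    n_eff <- min(length(x), length(y))
  }
  exact <- n_eff <= exact_max_n && !ties
  res <- suppressWarnings(
    stats::wilcox.test(x, y, paired = paired, exact = exact,
                       correct = !exact))
  list(statistic = unname(res$statistic), p = res$p.value,
       method = res$method, exact = exact,
       n = if (paired) n_eff else c(length(x), length(y)))
}

#' Pearson correlation with two-sided t-based p-value
#'
#' Complete pairs only; reported as exploratory and not corrected for
#' multiple comparisons.
#'
#' @param x,y Numeric vectors.
#' @return List: `r`, `p`, `n`, `df`.
#' @export
pearson_corr <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("constant input")
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x),
       df = unname(ct$parameter))
}
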