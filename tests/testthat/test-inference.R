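test_that("mixed ANOVA matches the sums-of-squares oracle on a toy design", {
  d <- data.frame(participant = rep(c("p1", "p2", "p3", "p4"), each = 2),
                  group = rep(c("a", "b"), each = 4),
                  session = rep(c("1", "2"), 4),
                  value = c(1, 2, 2, 3, 3, 5, 4, 6))
  a <- mixed_anova_2x2(d)
  # this design is exactly additive within subjects, so the within error is
  # 0 and the session/interaction F are degenerate: compare the SS
  # decomposition exactly, and F for the between-subject effect
  expect_equal(a$table$ss, c(12.5, 4.5, 0.5), tolerance = 1e-12)
  expect_equal(a$table$ss_error[1], 2, tolerance = 1e-12)
  expect_equal(a$table$ss_error[2], 0, tolerance = 1e-12)
  o <- anova_ss_oracle(d)
  expect_equal(a$table$F[1], o$F_group, tolerance = 1e-10)
  expect_equal(a$table$pes[1], o$pes_group, tolerance = 1e-10)
  expect_equal(a$table$df_num, c(1, 1, 1))
  expect_equal(a$table$df_den, c(2, 2, 2))
})

test_that("mixed ANOVA equals the oracle on non-degenerate random designs", {
  set.seed(19)
  for (rep in 1:10) {
    d <- random_balanced_design(sample(3:8, 1))
    a <- mixed_anova_2x2(d)
    o <- anova_ss_oracle(d)
    expect_equal(a$table$F, c(o$F_group, o$F_session, o$F_inter),
                 tolerance = 1e-8)
    expect_equal(a$table$pes, c(o$pes_group, o$pes_session, o$pes_inter),
                 tolerance = 1e-8)
  }
})

test_that("identical per-participant values across groups null the effects", {
  d <- data.frame(participant = rep(c("p1", "p2", "p3", "p4"), each = 2),
                  group = rep(c("a", "b"), each = 4),
                  session = rep(c("1", "2"), 4),
                  value = c(1, 2, 2, 4, 1, 2, 2, 4))
  a <- mixed_anova_2x2(d)
  expect_equal(a$table$F[a$table$effect == "group"], 0, tolerance = 1e-12)
  expect_equal(a$table$F[a$table$effect == "interaction"], 0,
               tolerance = 1e-12)
})

test_that("ANOVA statistics are invariant to additive shifts", {
  set.seed(20)
  d <- random_balanced_design(8)
  a1 <- mixed_anova_2x2(d)
  d$value <- d$value + 57.3
  a2 <- mixed_anova_2x2(d)
  expect_equal(a1$table$F, a2$table$F, tolerance = 1e-9)
  expect_equal(a1$table$pes, a2$table$pes, tolerance = 1e-9)
})

test_that("incomplete participants are dropped listwise with a log message", {
  set.seed(21)
  d <- random_balanced_design(5)
  extra <- data.frame(participant = "p99", group = "a", session = "1",
                      value = 3)
  expect_message(a <- mixed_anova_2x2(rbind(d, extra)), "p99")
  expect_equal(a$dropped, "p99")
  expect_equal(a$table$F, mixed_anova_2x2(d)$table$F)
  tiny <- d[d$participant %in% c("p01", "p06", "p07", "p08", "p09", "p10"), ]
  expect_error(mixed_anova_2x2(tiny), "at least 2 complete participants")
})

test_that("per-cell one-sample tests adjust p-values per Holm", {
  set.seed(22)
  d <- expand.grid(group = c("a", "b"), session = c("1", "2"),
                   rep = 1:10)
  d$value <- rnorm(nrow(d), mean = 0.8)
  res <- adjusted_one_sample_tests(d)
  expect_equal(nrow(res), 4)
  o <- order(res$p)
  holm <- pmin(1, cummax(res$p[o] * (4:1)))
  expect_equal(res$p_adj[o], holm)
  expect_true(all(res$p_adj >= res$p))
  # symmetric-around-zero cell: t = 0, p = 1, p_adj = 1
  d2 <- d
  d2$value[d2$group == "a" & d2$session == "1"] <- rep(c(-1, 1), 5)
  res2 <- adjusted_one_sample_tests(d2)
  r <- res2[res2$group == "a" & res2$session == "1", ]
  expect_equal(r$t, 0)
  expect_equal(r$p, 1)
  expect_equal(r$p_adj, 1)
})

test_that("strongly shifted cells all reach adjusted significance", {
  set.seed(23)
  d <- expand.grid(group = c("a", "b"), session = c("1", "2"), rep = 1:30)
  d$value <- rnorm(nrow(d), mean = -0.9)
  expect_true(all(adjusted_one_sample_tests(d)$p_adj < 0.05))
})

test_that("rank tests enumerate exactly for small complete separations", {
  r <- rank_tests(c(1, 2, 3), c(4, 5, 6), mode = "unpaired")
  expect_true(r$exact)
  expect_equal(r$p, 0.1)  # 2/20 orderings at n = 3, 3
  expect_equal(r$statistic, 0)
  swapped <- rank_tests(c(4, 5, 6), c(1, 2, 3), mode = "unpaired")
  expect_equal(swapped$statistic, 9)  # complement n1*n2 - W
  expect_equal(swapped$p, r$p)
  expect_error(rank_tests(c(1, 2, 3), c(1, 2, 3), mode = "paired"),
               "all paired differences are zero")
  big <- rank_tests(rnorm(30), rnorm(30), mode = "unpaired")
  expect_false(big$exact)
})

test_that("paired signed-rank test drops zero differences", {
  x <- c(5, 3, 8, 4, 9, 2)
  y <- c(5, 1, 6, 1, 4, 1)  # one zero difference
  r <- rank_tests(x, y, mode = "paired")
  expect_equal(r$n, 5)
  ref <- suppressWarnings(wilcox.test(x, y, paired = TRUE, exact = FALSE,
                                      correct = TRUE))
  expect_equal(r$p, ref$p.value)
})

test_that("Pearson correlation matches the covariance formula and guards", {
  x <- 1:10
  expect_equal(pearson_corr(x, 2 * x + 1)$r, 1, tolerance = 1e-12)
  expect_equal(pearson_corr(x, -x)$r, -1, tolerance = 1e-12)
  set.seed(24)
  a <- rnorm(50); b <- rnorm(50)
  r <- pearson_corr(a, b)
  r_oracle <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(r$r, r_oracle, tolerance = 1e-12)
  expect_error(pearson_corr(rep(1, 5), rnorm(5)), "constant")
  expect_error(pearson_corr(1:2, 2:3), "at least 3")
})

test_that("a programmed interaction effect at eta_p^2 ~ 0.17 is detectable", {
  # patient session-2 motor-noise multiplier 1.10 shifts mean |error| by
  # ~7 ms, the size that produces a partial eta squared near 0.17 at
  # n = 12/group; the rejection rate documents the power at the study scale
  set.seed(31)
  spec0 <- cohort_spec(n_per_group = 12, n_trials = 120, n_blocks = 2,
                       effects = NULL)
  truth <- sim_truth()
  truth_eff <- sim_truth(sigma_motor = truth$sigma_motor * 1.10)
  n_rep <- 100
  rej <- logical(n_rep)
  pes <- numeric(n_rep)
  for (r in seq_len(n_rep)) {
    cells <- expand.grid(participant = sprintf("p%02d", 1:24),
                         session = c("1", "2"), stringsAsFactors = FALSE)
    cells$group <- ifelse(as.integer(substring(cells$participant, 2)) <= 12,
                          "patient", "control")
    cells$value <- vapply(seq_len(nrow(cells)), function(i) {
      tt <- if (cells$group[i] == "patient" && cells$session[i] == "2")
        truth_eff else truth
      summarize_behavior(simulate_behavior(spec0, tt))$mean_abs_error
    }, numeric(1))
    a <- mixed_anova_2x2(cells)
    row <- a$table[a$table$effect == "interaction", ]
    rej[r] <- row$p < 0.05
    pes[r] <- row$pes
  }
  cat(sprintf("\n  power calibration: rejection rate %.2f, median pes %.3f\n",
              mean(rej), median(pes)))
  expect_gt(mean(rej), 0.25)
  expect_lt(median(pes), 0.5)
})
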