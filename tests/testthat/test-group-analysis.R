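# Independent oracle: textbook sums-of-squares decomposition for a balanced
# two-group, three-condition mixed design, written directly from the
# definitional formulas (no model-fitting machinery).
anova_oracle <- function(wide, group) {
  y <- as.matrix(wide)
  n <- nrow(y); k <- ncol(y); N <- n * k
  grand <- mean(y)
  subj_means <- rowMeans(y)
  cond_means <- colMeans(y)
  groups <- unique(group)
  g_means <- vapply(groups, function(g) mean(y[group == g, ]), 0)
  n_g <- vapply(groups, function(g) sum(group == g), 0)
  ss_between_subj <- k * sum((subj_means - grand)^2)
  ss_group <- k * sum(n_g * (g_means - grand)^2)
  ss_subj_within <- ss_between_subj - ss_group
  ss_cond <- n * sum((cond_means - grand)^2)
  ss_gc <- 0
  for (gi in seq_along(groups)) {
    for (ci in seq_len(k)) {
      cell <- mean(y[group == groups[gi], ci])
      ss_gc <- ss_gc + n_g[gi] *
        (cell - g_means[gi] - cond_means[ci] + grand)^2
    }
  }
  ss_total <- sum((y - grand)^2)
  ss_resid <- ss_total - ss_between_subj - ss_cond - ss_gc
  df_sw <- n - length(groups)
  df_resid <- df_sw * (k - 1)
  out <- list(
    F_group = (ss_group / (length(groups) - 1)) / (ss_subj_within / df_sw),
    F_cond = (ss_cond / (k - 1)) / (ss_resid / df_resid),
    F_gc = (ss_gc / ((length(groups) - 1) * (k - 1))) / (ss_resid / df_resid),
    pes_group = ss_group / (ss_group + ss_subj_within),
    pes_cond = ss_cond / (ss_cond + ss_resid),
    pes_gc = ss_gc / (ss_gc + ss_resid),
    df = c(k - 1, df_resid))
  lapply(out, unname)
}

fixture_long <- function(values, groups) {
  k <- ncol(values)
  tibble::tibble(
    participant_id = rep(sprintf("p%d", seq_len(nrow(values))), each = k),
    group = rep(groups, each = k),
    condition = rep(paste0("c", seq_len(k)), nrow(values)),
    value = as.vector(t(values)))
}

test_that("behavioral summaries compute the worked arithmetic fixture", {
  d <- tibble::tibble(
    participant_id = "p1", group = "g", condition = "positive",
    rt_s = c(0.5, 0.6, 0.8, 0.9), accuracy = c(1, 1, 0, 0))
  s <- summarize_behavior(d)
  expect_equal(s$mean_rt_correct_s, 0.55)
  expect_equal(s$error_rate_pct, 50)

  all_ok <- tibble::tibble(participant_id = rep(c("p1", "p2"), each = 3),
                           group = "g",
                           condition = rep(c("a", "b", "c"), 2),
                           rt_s = 0.5, accuracy = 1)
  expect_true(all(summarize_behavior(all_ok)$error_rate_pct == 0))

  no_correct <- tibble::tibble(participant_id = "p1", group = "g",
                               condition = "a", rt_s = c(0.5, 0.6),
                               accuracy = c(0, 0))
  expect_message(s2 <- summarize_behavior(no_correct), "zero correct")
  expect_true(is.na(s2$mean_rt_correct_s))
})

test_that("mixed ANOVA matches the definitional sums-of-squares oracle to 1e-8", {
  vals <- matrix(c(0.61, 0.72, 0.80,
                   0.55, 0.66, 0.69,
                   0.58, 0.63, 0.75,
                   0.70, 0.81, 0.95,
                   0.66, 0.79, 0.88,
                   0.72, 0.77, 0.99), nrow = 6, byrow = TRUE)
  groups <- rep(c("young", "older"), each = 3)
  long <- fixture_long(vals, groups)
  got <- mixed_anova(long)
  orc <- anova_oracle(vals, groups)
  expect_equal(got$F[got$effect == "group"], orc$F_group, tolerance = 1e-8)
  expect_equal(got$F[got$effect == "condition"], orc$F_cond, tolerance = 1e-8)
  expect_equal(got$F[got$effect == "group:condition"], orc$F_gc,
               tolerance = 1e-8)
  expect_equal(got$pes, c(orc$pes_group, orc$pes_cond, orc$pes_gc),
               tolerance = 1e-8)
  expect_equal(got$df_num[got$effect == "condition"], 2)
  expect_equal(got$df_den[got$effect == "condition"], 2 * (6 - 2))
})

test_that("the ANOVA is invariant to location shifts and reports study-sized df", {
  set.seed(14)
  vals <- matrix(rnorm(63 * 3, 1, 0.2), nrow = 63)
  groups <- rep(c("young", "older"), c(25, 38))
  f0 <- mixed_anova(fixture_long(vals, groups))
  f1 <- mixed_anova(fixture_long(vals + 5, groups))
  expect_equal(f0$F, f1$F, tolerance = 1e-8)
  # the study's cohort sizes give the printed degrees of freedom
  expect_equal(f0$df_num, c(1, 2, 2))
  expect_equal(f0$df_den, c(61, 122, 122))
})

test_that("planned PI contrasts have the stated zero cases and F = t^2 identity", {
  mk <- function(rec, nonrec, groups) {
    n <- length(rec)
    tibble::tibble(
      participant_id = rep(sprintf("p%d", 1:n), 2),
      group = rep(groups, 2),
      condition = rep(c("recent_negative", "nonrecent_negative"), each = n),
      value = c(rec, nonrec))
  }
  g <- rep(c("a", "b"), each = 4)
  same <- mk(rec = rep(0.9, 8), nonrec = rep(0.9, 8), g)
  ct <- planned_pi_contrast(same)
  expect_equal(ct$estimate[ct$effect == "pi_overall"], 0)
  expect_equal(ct$p[ct$effect == "pi_overall"], 1)

  set.seed(2)
  base <- runif(8, 0.8, 1.0)
  shift <- c(rep(0.1, 4), rep(0.1, 4))  # equal PI in both groups
  eq <- mk(rec = base + shift, nonrec = base, g)
  ct2 <- planned_pi_contrast(eq)
  expect_equal(ct2$estimate[ct2$effect == "pi_x_group"],
               mean((base + shift - base)[1:4]) - mean((base + shift - base)[5:8]))
  expect_equal(abs(ct2$estimate[ct2$effect == "pi_x_group"]), 0)

  set.seed(3)
  noisy <- mk(rec = rnorm(8, 1.0, 0.1), nonrec = rnorm(8, 0.9, 0.1), g)
  ct3 <- planned_pi_contrast(noisy)
  ia <- ct3[ct3$effect == "pi_x_group", ]
  expect_equal(ia$F, ia$t^2, tolerance = 1e-10)
  expect_equal(ia$df_den, 6)
  # oracle: pooled two-sample t on the PI differences
  wide <- tidyr::pivot_wider(noisy, names_from = "condition",
                             values_from = "value")
  d <- wide$recent_negative - wide$nonrecent_negative
  tt <- t.test(d[wide$group == "a"], d[wide$group == "b"], var.equal = TRUE)
  expect_equal(ia$t, unname(tt$statistic), tolerance = 1e-10)
  expect_equal(ia$p, tt$p.value, tolerance = 1e-10)
})

test_that("pooled t-test matches the closed form and the study's df", {
  # worked example, computed from the definitional formulas
  x <- c(5.1, 4.9, 5.6, 5.3)
  y <- c(4.2, 4.8, 4.4)
  res <- independent_t(c(x, y), rep(c("a", "b"), c(4, 3)))
  sp2 <- (3 * var(x) + 2 * var(y)) / 5
  t_manual <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / 4 + 1 / 3))
  expect_equal(res$t, t_manual, tolerance = 1e-10)
  expect_equal(res$df, 5)
  expect_equal(res$p, 2 * pt(-abs(t_manual), 5), tolerance = 1e-10)

  set.seed(4)
  res61 <- independent_t(rnorm(63), rep(c("young", "older"), c(25, 38)))
  expect_equal(res61$df, 61)

  same <- rep(c(1, 2), 6)
  res0 <- independent_t(same, rep(c("a", "b"), each = 6))
  expect_equal(res0$estimate, 0)
  expect_equal(res0$t, 0)
  expect_error(independent_t(rep(1, 8), rep(c("a", "b"), each = 4)),
               "pooled variance")
})
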