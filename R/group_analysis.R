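#' Per-participant behavioral summaries
#'
#' Mean correct-trial RT (seconds) and error rate (percent) per participant
#' and condition, the inputs to the group-level statistics. Cells without any
#' correct trial get a missing RT and are flagged with a message.
#'
#' @param data Behavioral tibble (post-cutoff) with `participant_id`,
#'   `group`, `condition`, `rt_s`, `accuracy`.
#' @return Tibble: `participant_id`, `group`, `condition`, `n_trials`,
#'   `error_rate_pct`, `mean_rt_correct_s`.
#' @export
summarize_behavior <- function(data) {
  out <- data |>
    dplyr::group_by(.data$participant_id, .data$group, .data$condition) |>
    dplyr::summarise(
      n_trials = dplyr::n(),
      error_rate_pct = 100 * (1 - mean(.data$accuracy)),
      mean_rt_correct_s = if (any(.data$accuracy == 1)) {
        mean(.data$rt_s[.data$accuracy == 1])
      } else {
        NA_real_
      },
      .groups = "drop")
  if (anyNA(out$mean_rt_correct_s)) {
    bad <- out[is.na(out$mean_rt_correct_s), ]
    message("cell(s) with zero correct trials flagged as missing: ",
            paste(bad$participant_id, bad$condition, sep = "/",
                  collapse = ", "))
  }
  out
}

# Greenhouse-Geisser epsilon from the pooled within-group covariance of the
# participant x condition matrix (double-centering form of Box's epsilon).
gg_epsilon <- function(wide, group) {
  k <- ncol(wide)
  centered <- wide
  for (g in unique(group)) {
    idx <- group == g
    centered[idx, ] <- scale(wide[idx, , drop = FALSE], scale = FALSE)
  }
  S <- crossprod(as.matrix(centered)) / (nrow(wide) - length(unique(group)))
  Sd <- sweep(S, 1, rowMeans(S))
  Sd <- sweep(Sd, 2, colMeans(S))
  Sd <- Sd + mean(S)
  sum(diag(Sd))^2 / ((k - 1) * sum(Sd^2))
}

#' Mixed repeated-measures ANOVA
#'
#' Classical mixed-design decomposition with one within-subject factor
#' (condition) and one between-subject factor (group): the between stratum
#' tests the group effect against participants-within-groups; the within
#' stratum tests condition and the condition x group interaction against the
#' participant x condition residual. Partial eta squared is
#' `SS_effect / (SS_effect + SS_error)` with each effect's own error stratum.
#' Greenhouse-Geisser epsilon and the corrected p-value are reported for the
#' within effects, but the uncorrected degrees of freedom are the primary
#' output.
#'
#' Participants with any missing condition cell are dropped listwise with a
#' message.
#'
#' @param values Long tibble with columns `participant_id`, `group`,
#'   `condition`, and the response in `value`.
#' @return Tibble: `effect`, `df_num`, `df_den`, `F`, `p`, `pes`,
#'   `gg_epsilon`, `p_gg`.
#' @export
mixed_anova <- function(values) {
  stopifnot(all(c("participant_id", "group", "condition", "value") %in%
                names(values)))
  wide <- values |>
    dplyr::select("participant_id", "group", "condition", "value") |>
    tidyr::pivot_wider(names_from = "condition", values_from = "value")
  cond_cols <- setdiff(names(wide), c("participant_id", "group"))
  complete <- stats::complete.cases(wide[cond_cols])
  if (!all(complete)) {
    message("dropping participant(s) with incomplete cells: ",
            paste(wide$participant_id[!complete], collapse = ", "))
    wide <- wide[complete, ]
  }
  if (min(table(wide$group)) < 2) {
    stop("mixed ANOVA needs at least 2 participants per group",
         call. = FALSE)
  }
  long <- tidyr::pivot_longer(wide, dplyr::all_of(cond_cols),
                              names_to = "condition", values_to = "value")
  long$participant_id <- factor(long$participant_id)
  long$group <- factor(long$group)
  long$condition <- factor(long$condition, levels = cond_cols)

  fit <- stats::aov(value ~ group * condition + Error(participant_id),
                    data = long)
  sm <- summary(fit)
  btw <- as.data.frame(sm[["Error: participant_id"]][[1]])
  wth <- as.data.frame(sm[["Error: Within"]][[1]])
  row_of <- function(tab, nm) tab[trimws(rownames(tab)) == nm, , drop = FALSE]
  eff_row <- function(tab, nm, err) {
    e <- row_of(tab, nm)
    tibble::tibble(effect = nm,
                   df_num = e$Df, df_den = err$Df,
                   F = e$`F value`, p = e$`Pr(>F)`,
                   pes = e$`Sum Sq` / (e$`Sum Sq` + err$`Sum Sq`))
  }
  err_b <- row_of(btw, "Residuals")
  err_w <- row_of(wth, "Residuals")
  out <- dplyr::bind_rows(
    eff_row(btw, "group", err_b),
    eff_row(wth, "condition", err_w),
    eff_row(wth, "group:condition", err_w))

  eps <- gg_epsilon(wide[cond_cols], wide$group)
  out$gg_epsilon <- c(NA, eps, eps)
  out$p_gg <- ifelse(is.na(out$gg_epsilon), NA,
                     stats::pf(out$F, out$df_num * out$gg_epsilon,
                               out$df_den * out$gg_epsilon,
                               lower.tail = FALSE))
  out
}

#' Planned proactive-interference contrasts
#'
#' The PI effect is the per-participant difference between the recent and
#' non-recent negative conditions. Reported are the overall effect and the
#' per-group effects (one-sample t-tests on the differences) and the
#' PI x group interaction: a pooled-variance two-sample t-test on the
#' per-participant differences between groups, with `F = t^2` on
#' `(1, N - 2)` degrees of freedom.
#'
#' @param values Long tibble (`participant_id`, `group`, `condition`,
#'   `value`) containing the `recent_negative` and `nonrecent_negative`
#'   conditions.
#' @param higher_is Direction convention only affects the sign of the
#'   estimate: the PI difference is `recent - nonrecent`.
#' @return Tibble of contrasts: `effect`, `estimate`, `t`, `F`, `df_num`,
#'   `df_den`, `p`.
#' @export
planned_pi_contrast <- function(values, higher_is = "recent_negative") {
  wide <- values |>
    dplyr::filter(.data$condition %in% c("recent_negative",
                                         "nonrecent_negative")) |>
    tidyr::pivot_wider(names_from = "condition", values_from = "value")
  stopifnot(all(c("recent_negative", "nonrecent_negative") %in% names(wide)))
  wide <- wide[stats::complete.cases(wide[c("recent_negative",
                                            "nonrecent_negative")]), ]
  pi_diff <- wide$recent_negative - wide$nonrecent_negative
  grp <- wide$group
  one <- function(label, x) {
    if (stats::sd(x) < 1e-14) {
      tt <- list(estimate = mean(x), statistic = 0,
                 parameter = length(x) - 1, p.value = 1)
    } else {
      tt <- stats::t.test(x, mu = 0)
    }
    tibble::tibble(effect = label, estimate = mean(x),
                   t = unname(tt$statistic), F = unname(tt$statistic)^2,
                   df_num = 1, df_den = length(x) - 1,
                   p = tt$p.value)
  }
  rows <- list(one("pi_overall", pi_diff))
  for (g in unique(grp)) {
    rows[[length(rows) + 1L]] <- one(paste0("pi_", g), pi_diff[grp == g])
  }
  if (length(unique(grp)) == 2) {
    g1 <- pi_diff[grp == unique(grp)[1]]
    g2 <- pi_diff[grp == unique(grp)[2]]
    est <- mean(g1) - mean(g2)
    if (stats::sd(c(g1 - mean(g1), g2 - mean(g2))) < 1e-14) {
      tval <- 0; pval <- 1
    } else {
      tt <- stats::t.test(g1, g2, var.equal = TRUE)
      tval <- unname(tt$statistic); pval <- tt$p.value
    }
    rows[[length(rows) + 1L]] <- tibble::tibble(
      effect = "pi_x_group", estimate = est, t = tval, F = tval^2,
      df_num = 1, df_den = length(pi_diff) - 2, p = pval)
  }
  dplyr::bind_rows(rows)
}

#' Independent-samples t-test (pooled variance)
#'
#' Equal-variance two-sample t-test, so the degrees of freedom are
#' `n1 + n2 - 2` (61 for groups of 25 and 38), matching the convention of
#' the group comparisons on boundary separation and nondecision time.
#'
#' @param x Numeric values.
#' @param group Two-level grouping vector aligned with `x`.
#' @return Tibble: `group1`, `group2`, `mean1`, `mean2`, `estimate`
#'   (mean1 - mean2), `t`, `df`, `p`.
#' @export
independent_t <- function(x, group) {
  lev <- unique(group)
  stopifnot(length(lev) == 2)
  x1 <- x[group == lev[1]]
  x2 <- x[group == lev[2]]
  stopifnot(length(x1) >= 2, length(x2) >= 2)
  pooled_var <- (sum((x1 - mean(x1))^2) + sum((x2 - mean(x2))^2)) /
    (length(x1) + length(x2) - 2)
  if (pooled_var <= 0) {
    stop("zero pooled variance: t-test undefined", call. = FALSE)
  }
  tt <- stats::t.test(x1, x2, var.equal = TRUE)
  tibble::tibble(group1 = lev[1], group2 = lev[2],
                 mean1 = mean(x1), mean2 = mean(x2),
                 estimate = mean(x1) - mean(x2),
                 t = unname(tt$statistic), df = unname(tt$parameter),
                 p = tt$p.value)
}
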