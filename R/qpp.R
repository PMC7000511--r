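#' Observed response proportions and RT quantiles
#'
#' Empirical quantile-probability summary: per condition and response
#' (correct / error), the response proportion and the RT quantiles at the
#' five standard probabilities, computed with the linear-interpolation
#' (type 7) convention. Cells with fewer than `min_n` RTs keep their
#' proportion but have their quantiles flagged as unreliable; empty cells are
#' flagged, never fabricated.
#'
#' @param data Behavioral tibble (post-cutoff) with `condition`, `rt_s`,
#'   `accuracy`.
#' @param probs Quantile probabilities.
#' @param min_n Minimum RTs per cell for reliable quantiles.
#' @return Tibble: `condition`, `response`, `n`, `prop`, `q10` ... `q90`,
#'   `reliable`.
#' @export
observed_quantiles <- function(data, probs = c(.1, .3, .5, .7, .9),
                               min_n = 5L) {
  rows <- list()
  for (cc in unique(data$condition)) {
    d <- data[data$condition == cc, ]
    for (resp in c("correct", "error")) {
      rt <- d$rt_s[d$accuracy == (resp == "correct")]
      n <- length(rt)
      qs <- if (n >= 1) {
        stats::quantile(rt, probs, type = 7, names = FALSE)
      } else {
        rep(NA_real_, length(probs))
      }
      reliable <- n >= min_n
      if (!reliable) qs <- rep(NA_real_, length(probs))
      row <- tibble::tibble(condition = cc, response = resp, n = n,
                            prop = n / nrow(d))
      qmat <- matrix(qs, nrow = 1,
                     dimnames = list(NULL, paste0("q", probs * 100)))
      rows[[length(rows) + 1L]] <-
        dplyr::bind_cols(row, tibble::as_tibble(qmat),
                         tibble::tibble(reliable = reliable))
    }
  }
  dplyr::bind_rows(rows)
}

#' Quantile-probability plot
#'
#' One panel per condition (columns) and grouping level (rows): response
#' proportion on the x-axis against the five RT quantiles on the y-axis,
#' error responses on the left branch and correct responses on the right.
#' Observed summaries are drawn as crosses, model-predicted summaries as
#' open circles.
#'
#' @param observed Quantile summary tibble ([observed_quantiles()] format),
#'   optionally with a `panel` column for row faceting.
#' @param predicted Matching tibble of model-predicted summaries.
#' @param file Optional output path (`.png` or `.svg`); written
#'   deterministically given the inputs.
#' @param width,height Device size in inches.
#' @return The ggplot object, invisibly if `file` is given.
#' @export
qpp_figure <- function(observed, predicted, file = NULL, width = 9,
                       height = 4 * max(1, length(unique(observed$panel %||% 1)))) {
  oc <- setdiff(unique(observed$condition), unique(predicted$condition))
  pc <- setdiff(unique(predicted$condition), unique(observed$condition))
  if (length(oc) + length(pc) > 0) {
    stop("condition mismatch between observed and predicted summaries: ",
         paste(c(oc, pc), collapse = ", "), call. = FALSE)
  }
  prep <- function(x, src) {
    qcols <- grep("^q\\d+$", names(x), value = TRUE)
    x$source <- src
    if (!"panel" %in% names(x)) x$panel <- ""
    tidyr::pivot_longer(x, dplyr::all_of(qcols), names_to = "quantile",
                        values_to = "rt_s")
  }
  dd <- dplyr::bind_rows(prep(observed, "observed"),
                         prep(predicted, "predicted"))
  dd <- dd[!is.na(dd$rt_s), ]
  gg <- ggplot2::ggplot(dd, ggplot2::aes(x = .data$prop, y = .data$rt_s,
                                         shape = .data$source)) +
    ggplot2::geom_point(size = 2.2, stroke = 0.8) +
    ggplot2::scale_shape_manual(values = c(observed = 4, predicted = 1)) +
    ggplot2::facet_grid(panel ~ condition) +
    ggplot2::labs(x = "response proportion", y = "RT quantile (s)",
                  shape = NULL) +
    ggplot2::theme_bw()
  if (!is.null(file)) {
    ggplot2::ggsave(file, gg, width = width, height = height, dpi = 150)
    return(invisible(gg))
  }
  gg
}

#' Group-averaged model-predicted quantile summary
#'
#' Predicts the quantile summary per participant from that participant's
#' fitted parameters, then averages response proportions and quantiles
#' across participants (the per-participant-then-average convention).
#'
#' @param fits Fit tibble from [fit_models()], one model only.
#' @param conditions Conditions to predict.
#' @param n_quad Quadrature nodes.
#' @return Tibble in [observed_quantiles()] format plus a `group` column.
#' @export
predicted_quantiles_cohort <- function(fits, conditions = ddm_conditions(),
                                       n_quad = 11L) {
  stopifnot(length(unique(fits$model_id)) == 1)
  per <- list()
  for (i in seq_len(nrow(fits))) {
    p <- fits$fit[[i]]$params
    for (cc in conditions) {
      q <- predicted_quantiles(p, cc, n_quad = n_quad)
      q$participant_id <- fits$participant_id[i]
      q$group <- fits$group[i]
      per[[length(per) + 1L]] <- q
    }
  }
  dplyr::bind_rows(per) |>
    dplyr::group_by(.data$group, .data$condition, .data$response) |>
    dplyr::summarise(dplyr::across(dplyr::matches("^prop$|^q\\d+$"),
                                   ~ mean(.x, na.rm = TRUE)),
                     reliable = all(.data$reliable), .groups = "drop")
}

#' Run the full analysis pipeline
#'
#' Synthesize (or load) behavioral data, apply the RT cutoffs, fit the
#' requested models per participant, select by BIC, run the group statistics
#' on behavior and on the winning model's parameters, and write the
#' quantile-probability summary and figure plus a manifest of seeds and
#' artifact paths.
#'
#' @param config A list (or path to a YAML file) with elements:
#'   `seed`, `outdir`, `models` (ids to fit), `cohort` (either `n_young` /
#'   `n_older` counts for the default reference cohort, with optional logical
#'   `between_sd`), `data_csv` (optional: load instead of synthesizing),
#'   `fit` (optional [fit_options()] overrides), `qpp_model` (model id used
#'   for the quantile-probability figure; default the cohort winner).
#' @return A list of artifacts (data, fits tibble, winners, ranking,
#'   statistics tables, qpp summaries, manifest), invisibly; everything is
#'   also written under `outdir`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  seed <- config$seed %||% 1L
  outdir <- config$outdir %||% stop("config$outdir is required", call. = FALSE)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  data <- stage("synthesize", {
    if (!is.null(config$data_csv)) {
      read_behavior(config$data_csv)
    } else {
      ch <- config$cohort %||% list()
      spec <- default_cohort_spec(n_young = ch$n_young %||% 25L,
                                  n_older = ch$n_older %||% 38L,
                                  seed = seed,
                                  between_sd = ch$between_sd %||% TRUE)
      synthesize_dataset(sample_cohort(spec), session_design(), seed = seed)
    }
  })

  cut <- stage("cutoffs", apply_rt_cutoffs(data))
  write_behavior(cut$data, file.path(outdir, "behavior.csv"))

  fit_args <- config$fit %||% list()
  if (is.null(fit_args$seed)) fit_args$seed <- seed
  fo <- do.call(fit_options, fit_args)
  models <- config$models %||% 1:6
  fits <- stage("fit", fit_models(cut$data, models = models, options = fo))
  fits_out <- fits[, setdiff(names(fits), "fit")]
  utils::write.csv(fits_out, file.path(outdir, "fits.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    lapply(seq_len(nrow(fits)), function(i) {
      f <- fits$fit[[i]]
      list(participant_id = f$participant_id, model_id = f$model_id,
           log_likelihood = f$log_likelihood, bic = f$bic,
           n_trials_used = f$n_trials_used, converged = f$converged,
           parameters = unclass(f$params))
    }),
    file.path(outdir, "fits.json"), auto_unbox = TRUE, digits = NA)

  winners <- stage("select", select_best(fits))
  ranking <- ranking_table(winners, models = models)
  utils::write.csv(ranking, file.path(outdir, "ranking.csv"),
                   row.names = FALSE)

  stats_out <- stage("group_stats", {
    beh <- summarize_behavior(cut$data)
    rt_long <- dplyr::transmute(beh, .data$participant_id, .data$group,
                                .data$condition,
                                value = .data$mean_rt_correct_s)
    err_long <- dplyr::transmute(beh, .data$participant_id, .data$group,
                                 .data$condition,
                                 value = .data$error_rate_pct)
    win_model <- ranking$model_id[ranking$rank == 1][1]
    wf <- fits[fits$model_id == win_model, ]
    drift_long <- dplyr::bind_rows(lapply(seq_len(nrow(wf)), function(i) {
      p <- wf$fit[[i]]$params
      tibble::tibble(participant_id = wf$participant_id[i],
                     group = wf$group[i], condition = p$conditions,
                     value = unname(p$v))
    }))
    par_scalar <- function(name) {
      vapply(seq_len(nrow(wf)), function(i) wf$fit[[i]]$params[[name]][[1]], 0)
    }
    list(behavior = beh,
         anova_rt = mixed_anova(rt_long),
         anova_err = mixed_anova(err_long),
         anova_drift = mixed_anova(drift_long),
         pi_rt = planned_pi_contrast(rt_long),
         pi_err = planned_pi_contrast(err_long),
         pi_drift = planned_pi_contrast(drift_long),
         t_boundary = independent_t(par_scalar("a"), wf$group),
         t_ter = independent_t(par_scalar("ter"), wf$group),
         winner_model = win_model)
  })
  for (nm in c("anova_rt", "anova_err", "anova_drift", "pi_rt", "pi_err",
               "pi_drift", "t_boundary", "t_ter")) {
    utils::write.csv(stats_out[[nm]],
                     file.path(outdir, paste0(nm, ".csv")), row.names = FALSE)
  }

  qpp <- stage("qpp", {
    qpp_model <- config$qpp_model %||% stats_out$winner_model
    obs <- cut$data |>
      dplyr::group_by(.data$group) |>
      dplyr::group_modify(~ observed_quantiles(.x)) |>
      dplyr::ungroup() |>
      dplyr::rename(panel = "group")
    pred <- predicted_quantiles_cohort(fits[fits$model_id == qpp_model, ]) |>
      dplyr::rename(panel = "group")
    fig <- file.path(outdir, "qpp.png")
    qpp_figure(obs, pred, file = fig)
    list(observed = obs, predicted = pred, figure = fig)
  })

  manifest <- list(seed = seed, models = models,
                   n_participants = length(unique(cut$data$participant_id)),
                   n_trials = nrow(cut$data),
                   excluded_fraction = cut$excluded_fraction,
                   winner_model = stats_out$winner_model,
                   r_version = as.character(getRversion()),
                   artifacts = list.files(outdir))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)

  invisible(list(data = cut$data, fits = fits, winners = winners,
                 ranking = ranking, stats = stats_out, qpp = qpp,
                 manifest = manifest))
}
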