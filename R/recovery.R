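#' Parameter-recovery study against the reference group means
#'
#' The core validation strategy when no human data are available: every
#' simulated participant receives exactly the published group-mean
#' parameters (between-subject SD zero, so the study isolates estimator bias
#' and variance), performs a full session of the default design, and is
#' refit with Model 1. Recovered parameters are averaged per group and
#' compared with the generating (published) values.
#'
#' @param groups Which reference groups to include.
#' @param n_per_group Simulated participants per group.
#' @param seed Master seed for sequence generation and simulation.
#' @param options [fit_options()] for the refits.
#' @param design [session_design()] for the sessions.
#' @return A list with `fits` (fit tibble), `summary` (tibble: group,
#'   parameter, reference value, mean recovered value, error), and `cohort`.
#' @export
recovery_study <- function(groups = c("young", "older"), n_per_group = 6L,
                           seed = 1L, options = fit_options(),
                           design = session_design()) {
  gspecs <- lapply(groups, function(g) {
    ref <- reference_group_params(g)
    list(label = g, n = n_per_group, means = ref$means,
         sds = list(v = ref$sds$v * 0, a = 0, ter = 0))
  })
  cohort <- sample_cohort(cohort_spec(gspecs, seed = seed))
  data <- synthesize_dataset(cohort, design, seed = seed)
  cut <- apply_rt_cutoffs(data)
  fits <- fit_models(cut$data, models = 1L, options = options)

  rows <- list()
  for (g in groups) {
    ref <- reference_group_params(g)
    fg <- fits[fits$group == g, ]
    rec <- function(fun) colMeans(do.call(rbind, lapply(fg$fit, fun)))
    v_rec <- rec(function(f) f$params$v)
    a_rec <- mean(vapply(fg$fit, function(f) f$params$a[[1]], 0))
    t_rec <- mean(vapply(fg$fit, function(f) f$params$ter[[1]], 0))
    ref_vals <- c(ref$means$v, a = unname(ref$means$a[[1]]),
                  ter = unname(ref$means$ter[[1]]))
    rec_vals <- c(v_rec, a = unname(a_rec), ter = unname(t_rec))
    rows[[g]] <- tibble::tibble(
      group = g,
      parameter = c(paste0("v_", names(ref$means$v)), "a", "ter"),
      reference = unname(ref_vals), recovered = unname(rec_vals),
      error = unname(rec_vals - ref_vals))
  }
  list(fits = fits, summary = dplyr::bind_rows(rows), cohort = cohort,
       data = cut$data)
}

#' Null-interaction study: equal proactive interference in drift
#'
#' Generates replicate two-group cohorts whose proactive-interference effect
#' in drift rate (non-recent minus recent negative drift) is exactly equal
#' across groups (the older group's recent-negative drift is set to its
#' non-recent drift minus the young group's PI effect), with the usual
#' between-subject dispersion; fits Model 1 per participant and tests the
#' PI x group interaction on the recovered drift rates. Under this null the
#' interaction should be non-significant at `alpha` in about `1 - alpha` of
#' replicates.
#'
#' @param n_replicates Number of replicate cohorts.
#' @param n_per_group Participants per group per cohort.
#' @param seed Master seed.
#' @param options [fit_options()] for the refits.
#' @param alpha Significance level for the interaction test.
#' @return A list with `per_replicate` (tibble: replicate, estimate, F, p,
#'   significant) and `nonsignificant_fraction`.
#' @export
null_pi_study <- function(n_replicates = 10L, n_per_group = 4L, seed = 1L,
                          options = fit_options(), alpha = 0.05) {
  young <- reference_group_params("young")
  older <- reference_group_params("older")
  pi_young <- young$means$v[["nonrecent_negative"]] -
    young$means$v[["recent_negative"]]
  v_old <- older$means$v
  v_old[["recent_negative"]] <- v_old[["nonrecent_negative"]] - pi_young
  older_means <- ddm_params(v = v_old, a = older$means$a,
                            ter = older$means$ter, eta = older$means$eta,
                            sz = older$means$sz, st = older$means$st)
  rows <- list()
  for (r in seq_len(n_replicates)) {
    rseed <- as.integer((as.numeric(seed) + 7919 * r) %% .Machine$integer.max)
    spec <- cohort_spec(list(
      list(label = "young", n = n_per_group, means = young$means,
           sds = young$sds),
      list(label = "older", n = n_per_group, means = older_means,
           sds = older$sds)), seed = rseed)
    data <- synthesize_dataset(sample_cohort(spec), session_design(),
                               seed = rseed)
    cut <- apply_rt_cutoffs(data)
    fits <- fit_models(cut$data, models = 1L, options = options)
    drifts <- dplyr::bind_rows(lapply(seq_len(nrow(fits)), function(i) {
      p <- fits$fit[[i]]$params
      tibble::tibble(participant_id = fits$participant_id[i],
                     group = fits$group[i], condition = p$conditions,
                     value = unname(p$v))
    }))
    ct <- planned_pi_contrast(drifts)
    ia <- ct[ct$effect == "pi_x_group", ]
    rows[[r]] <- tibble::tibble(replicate = r, estimate = ia$estimate,
                                F = ia$F, p = ia$p,
                                significant = ia$p < alpha)
  }
  per <- dplyr::bind_rows(rows)
  list(per_replicate = per,
       nonsignificant_fraction = mean(!per$significant))
}
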