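#' Apply response-time cutoffs
#'
#' Keeps trials with `low_s <= rt_s <= high_s` (defaults 0.200 s and
#' 7.000 s) and reports the excluded fraction.
#'
#' @param data Behavioral tibble with an `rt_s` column in seconds.
#' @param low_s,high_s Lower and upper cutoffs in seconds.
#' @return A list with `data` (filtered tibble), `excluded_fraction`, and
#'   `n_excluded`.
#' @export
apply_rt_cutoffs <- function(data, low_s = 0.200, high_s = 7.000) {
  stopifnot(nrow(data) > 0, "rt_s" %in% names(data))
  keep <- data$rt_s >= low_s & data$rt_s <= high_s
  out <- data[keep, , drop = FALSE]
  if ("participant_id" %in% names(data)) {
    gone <- setdiff(unique(data$participant_id), unique(out$participant_id))
    if (length(gone) > 0) {
      stop("all trials excluded by RT cutoffs for participant(s): ",
           paste(gone, collapse = ", "), call. = FALSE)
    }
  } else if (nrow(out) == 0) {
    stop("all trials excluded by RT cutoffs", call. = FALSE)
  }
  list(data = out, excluded_fraction = mean(!keep), n_excluded = sum(!keep))
}

# EZ-style moment estimators for one condition: accuracy, mean and variance
# of correct RTs give v, a and ter in closed form (diffusion constant s).
ez_condition <- function(accuracy, rt_correct, s, n) {
  pc <- mean(accuracy)
  # edge correction for accuracies of exactly 0, 1/2 or 1
  if (pc >= 1) pc <- 1 - 1 / (2 * n)
  if (pc <= 0) pc <- 1 / (2 * n)
  if (abs(pc - 0.5) < 1e-12) pc <- 0.5 + 1 / (2 * n)
  mrt <- mean(rt_correct)
  vrt <- stats::var(rt_correct)
  if (!is.finite(vrt) || vrt <= 1e-6) vrt <- 1e-3
  L <- stats::qlogis(pc)
  x <- L * (L * pc^2 - L * pc + pc - 0.5) / vrt
  v <- sign(pc - 0.5) * s * x^(1 / 4)
  a <- s^2 * L / v
  y <- -v * a / s^2
  mdt <- (a / (2 * v)) * (1 - exp(y)) / (1 + exp(y))
  ter <- mrt - mdt
  list(v = v, a = a, ter = ter, mrt = mrt)
}

#' Moment-based starting values for the simplex search
#'
#' Computes EZ-style closed-form estimates of drift rate, boundary
#' separation and nondecision time per condition from accuracy and the mean
#' and variance of correct response times, then averages the estimates of
#' parameters that the model holds fixed across conditions. Intertrial
#' variabilities start at `eta = 0.1`, `sz = 0.02`, `st = 0.1`; the bias
#' starts at `w = 0.5`. The result always satisfies the parameter
#' invariants. A warning is issued when a condition has fewer than 40
#' trials.
#'
#' @param data Behavioral tibble for one participant (post-cutoff) with
#'   `condition`, `rt_s`, `accuracy`.
#' @param spec A [model_spec()].
#' @param s Diffusion constant.
#' @return A [ddm_params()] object usable as the search start.
#' @export
initialize_parameters <- function(data, spec, s = 0.1) {
  conds <- spec$conditions
  n_cond <- table(factor(data$condition, levels = conds))
  if (any(n_cond < 40)) {
    warning("fewer than 40 trials in condition(s): ",
            paste(names(n_cond)[n_cond < 40], collapse = ", "),
            call. = FALSE)
  }
  ez <- lapply(conds, function(cc) {
    d <- data[data$condition == cc, ]
    rtc <- d$rt_s[d$accuracy == 1]
    if (length(rtc) < 2) rtc <- d$rt_s
    ez_condition(d$accuracy, rtc, s, nrow(d))
  })
  v <- vapply(ez, `[[`, 0, "v")
  a <- vapply(ez, `[[`, 0, "a")
  ter <- vapply(ez, `[[`, 0, "ter")
  mrt <- vapply(ez, `[[`, 0, "mrt")
  # guard rails: positive boundary at the task's scale, nondecision time
  # positive and below the observed mean RT
  a <- pmin(pmax(a, 0.03), 1.0)
  ter <- pmin(pmax(ter, 0.06), pmax(0.061, 0.9 * mrt))
  if (!("a" %in% spec$per_condition)) a <- rep(mean(a), length(conds))
  if (!("ter" %in% spec$per_condition)) ter <- rep(mean(ter), length(conds))
  sz0 <- pmin(0.02, 0.5 * SZ_FRAC * a)
  if (!("sz" %in% spec$per_condition)) sz0 <- rep(min(sz0), length(conds))
  st0 <- pmin(0.1, ter)
  if (!("st" %in% spec$per_condition)) st0 <- rep(min(st0), length(conds))
  z <- if (spec$bias) rep(min(a) / 2, length(conds)) else a / 2
  ddm_params(v = v, a = a, ter = ter, eta = 0.1, z = z, sz = sz0, st = st0,
             s = s, conditions = conds)
}

#' Fitting options
#'
#' @param n_restarts Number of simplex restarts; the first starts from the
#'   moment-based initialization, later ones from jittered copies of it.
#' @param seed Integer seed governing the jitter (fits are deterministic
#'   given data, spec and seed).
#' @param tolerance Relative convergence tolerance on the log-likelihood.
#' @param maxit Maximum simplex iterations per restart; default `400 * dim`
#'   (the simplex on 10-19 dimensions typically converges within 250-300
#'   iterations per dimension).
#' @param n_quad Gauss-Legendre nodes per variability dimension.
#' @param dfloor Density floor applied inside the likelihood.
#' @param jitter_sd SD of the Gaussian jitter on the unconstrained scale.
#' @return A `fit_options` list.
#' @export
fit_options <- function(n_restarts = 5L, seed = 1L, tolerance = 1e-6,
                        maxit = NULL, n_quad = 11L, dfloor = 1e-10,
                        jitter_sd = 0.25) {
  structure(list(n_restarts = as.integer(n_restarts), seed = as.integer(seed),
                 tolerance = tolerance, maxit = maxit,
                 n_quad = as.integer(n_quad), dfloor = dfloor,
                 jitter_sd = jitter_sd),
            class = "fit_options")
}

# Trial-level vectors entering the likelihood. Unbiased models are
# accuracy-coded (upper boundary = correct response, drift +v); biased models
# are stimulus-coded (upper boundary = "positive" response, negative
# conditions drift at -v, shared starting point z).
likelihood_frame <- function(data, spec, params) {
  cond <- data$condition
  if (spec$bias) {
    if (!"response" %in% names(data)) {
      stop("biased models need a `response` column (positive/negative)",
           call. = FALSE)
    }
    upper <- as.integer(data$response == "positive")
    v_eff <- stimulus_coded_drift(params, cond)
  } else {
    upper <- as.integer(data$accuracy == 1)
    v_eff <- unname(params$v[cond])
  }
  list(t = data$rt_s, upper = upper, v = v_eff,
       eta = unname(params$eta[cond]), a = unname(params$a[cond]),
       w = unname(params$z[cond] / params$a[cond]),
       sz = unname(params$sz[cond]), ter = unname(params$ter[cond]),
       st = unname(params$st[cond]))
}

#' Log-likelihood of a participant's data under a parameter set
#'
#' Sum over trials of the log of the full defective density at the observed
#' (RT, response), with densities floored at `dfloor` so outlier trials can
#' never drive the likelihood to minus infinity.
#'
#' @param data Behavioral tibble for one participant (post-cutoff).
#' @param params A [ddm_params()] object.
#' @param spec A [model_spec()] (decides the response coding).
#' @param n_quad,dfloor See [fit_options()].
#' @return Scalar log-likelihood.
#' @export
log_likelihood <- function(data, params, spec, n_quad = 11L, dfloor = 1e-10) {
  validate_ddm_params(params)
  fr <- likelihood_frame(data, spec, params)
  gl <- gauss_legendre(n_quad)
  -ddm_nll_cpp(fr$t, fr$upper, fr$v, fr$eta, fr$a, fr$w, fr$sz, fr$ter,
               fr$st, params$s, gl$x, gl$w, 1e-10, dfloor)
}

#' Fit one participant by maximum likelihood
#'
#' Nelder-Mead simplex search on an unconstrained transformed space (log for
#' positive parameters, logistic for bounded ones, so the optimizer can never
#' propose an invalid parameter set), best of `n_restarts` jittered
#' initializations. The Bayesian information criterion is computed from the
#' fitted log-likelihood, the model's free-parameter count and the number of
#' trials actually fitted.
#'
#' @param data Behavioral tibble for one participant, already filtered by
#'   [apply_rt_cutoffs()].
#' @param spec A [model_spec()].
#' @param options A [fit_options()] list.
#' @param participant_id Optional id stored in the result.
#' @return A `ddm_fit` list: `participant_id`, `model_id`, `params`,
#'   `log_likelihood`, `n_trials_used`, `bic`, `n_restarts`, `converged`,
#'   `best_restart`.
#' @export
fit_participant <- function(data, spec, options = fit_options(),
                            participant_id = NA_character_) {
  stopifnot(inherits(spec, "model_spec"), nrow(data) > 0)
  init <- initialize_parameters(data, spec, s = 0.1)
  theta0 <- params_to_theta(spec, init)
  gl <- gauss_legendre(options$n_quad)
  s <- init$s

  nll_fun <- function(theta) {
    p <- theta_to_params(spec, theta)
    fr <- likelihood_frame(data, spec, p)
    ddm_nll_cpp(fr$t, fr$upper, fr$v, fr$eta, fr$a, fr$w, fr$sz, fr$ter,
                fr$st, s, gl$x, gl$w, 1e-10, options$dfloor)
  }

  dim <- length(theta0)
  maxit <- options$maxit %||% (400L * dim)
  best <- NULL
  converged <- FALSE
  restart_log <- numeric(options$n_restarts)
  for (r in seq_len(options$n_restarts)) {
    set.seed(options$seed + 1000L * (r - 1L))
    start <- if (r == 1) theta0 else
      theta0 + stats::rnorm(dim, 0, options$jitter_sd)
    opt <- stats::optim(start, nll_fun, method = "Nelder-Mead",
                        control = list(maxit = maxit,
                                       reltol = options$tolerance))
    restart_log[r] <- -opt$value
    if (opt$convergence == 0) converged <- TRUE
    if (is.null(best) || opt$value < best$value) {
      best <- opt
      best$restart <- r
    }
  }
  params <- theta_to_params(spec, best$par)
  ll <- -best$value
  n <- nrow(data)
  structure(list(participant_id = participant_id, model_id = spec$id,
                 params = params, log_likelihood = ll, n_trials_used = n,
                 bic = bic(ll, spec$n_free, n),
                 n_restarts = options$n_restarts, converged = converged,
                 best_restart = best$restart, restart_loglik = restart_log,
                 init = init),
            class = "ddm_fit")
}

#' @export
print.ddm_fit <- function(x, ...) {
  cat(sprintf("Model %d fit for %s: logLik = %.2f, BIC = %.2f (n = %d, %s)\n",
              x$model_id, x$participant_id, x$log_likelihood, x$bic,
              x$n_trials_used,
              if (x$converged) "converged" else "NOT converged"))
  print(x$params)
  invisible(x)
}

#' Fit a set of models to every participant in a dataset
#'
#' @param data Behavioral tibble (post-cutoff) with `participant_id`.
#' @param models Integer vector of model ids to fit.
#' @param options A [fit_options()] list.
#' @param quiet Suppress progress messages.
#' @return A tibble with one row per participant x model: `participant_id`,
#'   `group` (if present), `model_id`, `n_free`, `log_likelihood`, `bic`,
#'   `converged`, and a `fit` list-column of `ddm_fit` objects.
#' @export
fit_models <- function(data, models = 1:6, options = fit_options(),
                       quiet = TRUE) {
  ids <- unique(data$participant_id)
  rows <- list()
  for (pid in ids) {
    d <- data[data$participant_id == pid, ]
    grp <- if ("group" %in% names(d)) d$group[1] else NA_character_
    for (m in models) {
      spec <- model_spec(m)
      if (!quiet) message(sprintf("fitting %s, Model %d (%d trials)",
                                  pid, m, nrow(d)))
      fit <- fit_participant(d, spec, options, participant_id = pid)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        participant_id = pid, group = grp, model_id = m,
        n_free = spec$n_free, log_likelihood = fit$log_likelihood,
        bic = fit$bic, converged = fit$converged, fit = list(fit))
    }
  }
  dplyr::bind_rows(rows)
}
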