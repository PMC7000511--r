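#' Simulator options
#'
#' @param dt Euler-Maruyama step in seconds (default 1e-4; halving it should
#'   change nothing beyond Monte-Carlo error).
#' @param max_t Absorption cap in seconds; non-absorbed paths are redrawn and
#'   counted (their rate must stay below 0.1%).
#' @param seed Optional integer seed applied before simulation.
#' @return A `sim_options` list.
#' @export
sim_options <- function(dt = 1e-4, max_t = 10, seed = NULL) {
  stopifnot(dt > 0, max_t > 0)
  structure(list(dt = dt, max_t = max_t, seed = seed), class = "sim_options")
}

# Stimulus-coded effective drift: positive-condition trials drift toward the
# upper ("positive") boundary at +v, negative-condition trials toward the
# lower ("negative") boundary at -v.
stimulus_coded_drift <- function(params, condition) {
  sign <- ifelse(condition == "positive", 1, -1)
  sign * params$v[condition]
}

#' Simulate diffusion trials for one condition
#'
#' Draws `n` trials under the full DDM for a single condition: per trial the
#' drift is drawn from N(v, eta), the start from U(z +/- sz/2) and the
#' nondecision time from U(ter +/- st/2), then the accumulator is integrated
#' by Euler-Maruyama until absorption. The upper boundary carries the drift's
#' positive direction; with `correct_upper = TRUE` (default) the returned
#' `accuracy` marks upper-boundary absorptions as correct.
#'
#' @param params A [ddm_params()] object.
#' @param condition Condition label.
#' @param n Number of trials.
#' @param options [sim_options()].
#' @return Tibble with `rt_s`, `response` (`"upper"`/`"lower"`), `accuracy`,
#'   plus an attribute `n_redraw`.
#' @export
simulate_condition <- function(params, condition, n, options = sim_options()) {
  validate_ddm_params(params)
  stopifnot(condition %in% params$conditions, n >= 1)
  if (!is.null(options$seed)) set.seed(options$seed)
  cc <- condition
  rep_n <- function(x) rep(x[[cc]], n)
  sim <- ddm_sim_cpp(rep_n(params$v), rep_n(params$eta), rep_n(params$a),
                     rep_n(params$z), rep_n(params$sz), rep_n(params$ter),
                     rep_n(params$st), params$s, options$dt, options$max_t)
  check_redraws(sim$n_redraw, n)
  out <- tibble::tibble(rt_s = sim$rt,
                        response = ifelse(sim$upper == 1, "upper", "lower"),
                        accuracy = as.integer(sim$upper == 1))
  attr(out, "n_redraw") <- sim$n_redraw
  out
}

check_redraws <- function(n_redraw, n) {
  if (n_redraw > 0.001 * n) {
    warning(sprintf("%d of %d simulated paths were not absorbed by max_t and were redrawn (> 0.1%%)",
                    n_redraw, n), call. = FALSE)
  }
  invisible(n_redraw)
}

#' Simulate a behavioral dataset for a trial sequence
#'
#' One simulated record per trial in `trials`, with the condition taken from
#' each trial and stimulus-coded drifts (upper boundary = "positive"
#' response). Reproducible under a fixed seed in `options`.
#'
#' @param params A [ddm_params()] object for the simulated participant.
#' @param trials Trial tibble from [generate_session()].
#' @param options [sim_options()].
#' @return Tibble: `block`, `trial`, `condition`, `response` (`"positive"`/
#'   `"negative"`), `rt_s`, `accuracy`.
#' @export
simulate_dataset <- function(params, trials, options = sim_options()) {
  validate_ddm_params(params)
  stopifnot(all(trials$condition %in% params$conditions))
  if (!is.null(options$seed)) set.seed(options$seed)
  cond <- trials$condition
  v_eff <- stimulus_coded_drift(params, cond)
  sim <- ddm_sim_cpp(v_eff, params$eta[cond], params$a[cond], params$z[cond],
                     params$sz[cond], params$ter[cond], params$st[cond],
                     params$s, options$dt, options$max_t)
  check_redraws(sim$n_redraw, nrow(trials))
  response <- ifelse(sim$upper == 1, "positive", "negative")
  tibble::tibble(block = trials$block, trial = trials$trial,
                 condition = cond, response = response, rt_s = sim$rt,
                 accuracy = as.integer(response == trials$correct_response))
}
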