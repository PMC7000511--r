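#' First-passage-time density of the simple diffusion process
#'
#' Defective density of the decision time at one boundary for a diffusion
#' process with constant drift `v` (toward the upper boundary), boundary
#' separation `a`, starting point `z` and diffusion constant `s`, without
#' intertrial variability and without nondecision time. Integrating the upper
#' and lower densities over all `t` gives 1; each one alone integrates to
#' that boundary's absorption probability.
#'
#' The density uses both the small-time and the large-time series expansion,
#' switching adaptively to whichever needs fewer terms at truncation
#' tolerance 1e-10.
#'
#' @param t Decision times in seconds (vectorized), all > 0.
#' @param boundary `"upper"` or `"lower"`.
#' @param v Drift rate toward the upper boundary.
#' @param a Boundary separation (> 0).
#' @param z Starting point (0 < z < a); default `a / 2`.
#' @param s Diffusion constant (default 0.1).
#' @return Numeric vector of defective densities (1/s).
#' @examples
#' # symmetric, zero drift: each boundary absorbs half the mass
#' integrate(wfpt_density, 0, Inf, boundary = "upper", v = 0, a = 0.1)$value
#' @export
wfpt_density <- function(t, boundary = c("upper", "lower"), v, a, z = a / 2,
                         s = 0.1) {
  boundary <- match.arg(boundary)
  if (any(!is.finite(t)) || any(t <= 0)) {
    stop("decision times `t` must be finite and > 0", call. = FALSE)
  }
  p <- ddm_params(v = v, a = a, ter = 0, z = z, s = s, conditions = "c")
  n <- length(t)
  gl <- gauss_legendre(1L)
  ddm_density_cpp(t, rep(as.integer(boundary == "upper"), n),
                  rep(p$v, n), rep(0, n), rep(p$a, n), rep(p$z / p$a, n),
                  rep(0, n), rep(0, n), rep(0, n), p$s,
                  gl$x, gl$w, 1e-10)
}

#' Full DDM density with intertrial variabilities
#'
#' Defective density of an observed response time under the full diffusion
#' decision model: Gaussian intertrial drift variability (`eta`) is
#' integrated analytically; the uniform starting-point (`sz`) and
#' nondecision-time (`st`) variabilities are integrated by fixed-order
#' Gauss-Legendre quadrature. With `eta = sz = st = 0` the result equals
#' `wfpt_density(t - ter, ...)` exactly.
#'
#' @param t Observed response times in seconds (vectorized).
#' @param response `"upper"` or `"lower"`: which boundary was reached.
#' @param params A [ddm_params()] object.
#' @param condition Condition label selecting the per-condition parameters.
#' @param n_quad Number of quadrature nodes per variability dimension.
#' @return Numeric vector of defective densities (1/s). Times at or below the
#'   lower edge of the nondecision support have density 0.
#' @export
full_density <- function(t, response = c("upper", "lower"), params, condition,
                         n_quad = 11L) {
  response <- match.arg(response)
  validate_ddm_params(params)
  stopifnot(condition %in% params$conditions)
  cc <- condition
  n <- length(t)
  gl <- gauss_legendre(n_quad)
  ddm_density_cpp(t, rep(as.integer(response == "upper"), n),
                  rep(params$v[[cc]], n), rep(params$eta[[cc]], n),
                  rep(params$a[[cc]], n),
                  rep(params$z[[cc]] / params$a[[cc]], n),
                  rep(params$sz[[cc]], n), rep(params$ter[[cc]], n),
                  rep(params$st[[cc]], n), params$s, gl$x, gl$w, 1e-10)
}

# Closed-form absorption probability at the upper boundary for constant drift
# (no variabilities): P(upper) = (1 - exp(-2 v z / s^2)) / (1 - exp(-2 v a / s^2)),
# evaluated stably on both drift signs; the zero-drift limit is z / a.
p_upper_constant <- function(v, a, z, s = 0.1) {
  u <- 2 * v / s^2
  if (abs(u) * a < 1e-10) return(z / a)
  if (v > 0) {
    expm1(-u * z) / expm1(-u * a)
  } else {
    (expm1(u * a) - expm1(u * (a - z))) / expm1(u * a)
  }
}

#' Probability of a correct (upper-boundary) response
#'
#' Absorption probability at the upper boundary under the full model:
#' the closed-form constant-drift probability averaged over the Gaussian
#' drift distribution (adaptive quadrature) and the uniform starting-point
#' distribution (Gauss-Legendre). Nondecision variability does not affect
#' choice.
#'
#' @inheritParams full_density
#' @return Scalar probability in (0, 1).
#' @export
choice_probability <- function(params, condition, n_quad = 11L) {
  validate_ddm_params(params)
  stopifnot(condition %in% params$conditions)
  cc <- condition
  v <- params$v[[cc]]; eta <- params$eta[[cc]]; a <- params$a[[cc]]
  z <- params$z[[cc]]; sz <- params$sz[[cc]]; s <- params$s
  over_z <- function(v1) {
    if (sz <= 0) return(p_upper_constant(v1, a, z, s))
    gl <- gauss_legendre(n_quad)
    zs <- z + sz / 2 * gl$x
    sum(gl$w / 2 * vapply(zs, function(zz) p_upper_constant(v1, a, zz, s), 0))
  }
  if (eta <= 0) return(over_z(v))
  f <- function(u) {
    vapply(u, over_z, 0) * stats::dnorm(u, v, eta)
  }
  stats::integrate(f, v - 8 * eta, v + 8 * eta, rel.tol = 1e-10)$value
}

# Defective CDF of the full density on a time grid (trapezoidal cumulative
# integral), one boundary. Grid spans the nondecision support up to t_max.
defective_cdf_grid <- function(params, condition, response, t_max = NULL,
                               n_grid = 4000L, n_quad = 11L) {
  cc <- condition
  lo <- params$ter[[cc]] - params$st[[cc]] / 2
  if (is.null(t_max)) {
    # decision-time scale is (a/s)^2 seconds; run far into the tail
    t_max <- params$ter[[cc]] + params$st[[cc]] / 2 +
      12 * (params$a[[cc]] / params$s)^2
  }
  t <- seq(lo, t_max, length.out = n_grid)
  f <- full_density(t, response, params, cc, n_quad = n_quad)
  dt <- diff(t)
  cdf <- c(0, cumsum((f[-1] + f[-length(f)]) / 2 * dt))
  list(t = t, cdf = cdf)
}

#' Model-predicted response proportions and RT quantiles
#'
#' Inverts the defective CDF of the full model per response boundary to give
#' the response proportion and the RT quantiles at the requested
#' probabilities, the model-side summary used in quantile-probability plots.
#'
#' @inheritParams full_density
#' @param probs Quantile probabilities (default the five standard ones).
#' @param boundaries Named mapping of `correct` / `error` responses to
#'   boundaries; the default treats the upper boundary as the correct
#'   response (the coding used by the unbiased models).
#' @param min_p Response proportions below this are flagged unreliable and
#'   their quantiles set to `NA` rather than fabricated.
#' @return A tibble with one row per (condition, response): `prop`, one
#'   column per quantile (`q10`, ..., `q90`), and `reliable`.
#' @export
predicted_quantiles <- function(params, condition,
                                probs = c(.1, .3, .5, .7, .9),
                                boundaries = c(correct = "upper",
                                               error = "lower"),
                                min_p = 0.001, n_quad = 11L) {
  validate_ddm_params(params)
  rows <- lapply(names(boundaries), function(resp) {
    g <- defective_cdf_grid(params, condition, boundaries[[resp]],
                            n_quad = n_quad)
    p_resp <- g$cdf[length(g$cdf)]
    if (p_resp < min_p) {
      qs <- rep(NA_real_, length(probs))
      ok <- FALSE
    } else {
      qs <- stats::approx(g$cdf, g$t, xout = probs * p_resp, ties = "ordered",
                          rule = 2)$y
      ok <- TRUE
    }
    tibble::tibble(condition = condition, response = resp, prop = p_resp,
                   prob = list(probs), q = list(qs), reliable = ok)
  })
  out <- dplyr::bind_rows(rows)
  qmat <- do.call(rbind, out$q)
  colnames(qmat) <- paste0("q", probs * 100)
  dplyr::bind_cols(out[c("condition", "response", "prop")],
                   tibble::as_tibble(qmat), out["reliable"])
}
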