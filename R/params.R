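#' Construct a full DDM parameter set
#'
#' Bundles the parameters of the diffusion decision model with intertrial
#' variabilities, expanded per task condition. Evidence-scale parameters
#' (`v`, `eta`, `a`, `z`, `sz`) are in evidence units with diffusion constant
#' `s`; temporal parameters (`ter`, `st`) are in seconds.
#'
#' Each of `v`, `eta`, `a`, `z`, `sz`, `ter`, `st` may be a scalar (shared
#' across conditions) or a vector with one entry per condition; scalars are
#' recycled. `z` defaults to `a / 2` (unbiased start).
#'
#' @param v Drift rate(s), signed toward the upper boundary (evidence units/s).
#' @param a Boundary separation(s), > 0.
#' @param ter Nondecision time(s), seconds.
#' @param eta Intertrial standard deviation(s) of the drift rate, >= 0.
#' @param z Starting point(s), strictly between 0 and `a`; default `a / 2`.
#' @param sz Intertrial range(s) of the starting point (uniform support
#'   width); `z - sz/2 > 0` and `z + sz/2 < a` must hold.
#' @param st Intertrial range(s) of the nondecision time (seconds);
#'   `ter - st/2 >= 0` must hold.
#' @param s Diffusion constant; fixed at 0.1 by convention.
#' @param conditions Character vector of condition labels.
#'
#' @return An object of class `ddm_params`: a list of named per-condition
#'   numeric vectors plus the scalar `s`.
#' @examples
#' p <- ddm_params(v = c(0.366, 0.290, 0.230), a = 0.176, ter = 0.304,
#'                 eta = 0.1, sz = 0.02, st = 0.1)
#' p$v
#' @export
ddm_params <- function(v, a, ter, eta = 0, z = NULL, sz = 0, st = 0, s = 0.1,
                       conditions = NULL) {
  conditions <- conditions %||% names(v) %||% ddm_conditions()[seq_along(v)]
  nc <- length(conditions)
  expand <- function(x, nm) {
    if (length(x) == 1L) x <- rep(x, nc)
    if (length(x) != nc) {
      stop(sprintf("`%s` must have length 1 or %d, got %d", nm, nc, length(x)),
           call. = FALSE)
    }
    stats::setNames(as.numeric(x), conditions)
  }
  a <- expand(a, "a")
  z <- if (is.null(z)) a / 2 else expand(z, "z")
  p <- structure(
    list(v = expand(v, "v"), eta = expand(eta, "eta"), a = a, z = z,
         sz = expand(sz, "sz"), ter = expand(ter, "ter"),
         st = expand(st, "st"), s = as.numeric(s), conditions = conditions),
    class = "ddm_params")
  validate_ddm_params(p)
  p
}

#' Validate a DDM parameter set
#'
#' Checks the structural invariants: positive boundary separation, a starting
#' point strictly inside the boundaries even at the extremes of its uniform
#' variability range, nonnegative variabilities, and a nondecision-time range
#' that keeps its lower support nonnegative.
#'
#' @param p A `ddm_params` object.
#' @return `p`, invisibly; stops with an informative message on violation.
#' @export
validate_ddm_params <- function(p) {
  stopifnot(inherits(p, "ddm_params"))
  bad <- function(cond, msg) if (any(cond)) stop(msg, call. = FALSE)
  bad(!is.finite(unlist(p[c("v", "eta", "a", "z", "sz", "ter", "st", "s")])),
      "DDM parameters must be finite")
  bad(p$s <= 0, "diffusion constant s must be > 0")
  bad(p$a <= 0, "boundary separation a must be > 0")
  bad(p$eta < 0, "drift variability eta must be >= 0")
  bad(p$sz < 0 | p$st < 0, "variability ranges sz, st must be >= 0")
  bad(p$z <= 0 | p$z >= p$a, "starting point z must satisfy 0 < z < a")
  bad(p$z - p$sz / 2 <= 0 | p$z + p$sz / 2 >= p$a,
      "starting-point range sz must keep z +/- sz/2 inside (0, a)")
  bad(p$ter - p$st / 2 < 0,
      "nondecision range st must keep ter - st/2 >= 0")
  invisible(p)
}

#' @export
print.ddm_params <- function(x, ...) {
  cat("DDM parameter set (s =", format(x$s), ")\n")
  m <- rbind(v = x$v, eta = x$eta, a = x$a, z = x$z, sz = x$sz,
             ter = x$ter, st = x$st)
  print(round(m, 4))
  invisible(x)
}

#' Serialize / deserialize parameter sets as JSON
#'
#' @param p A `ddm_params` object.
#' @param txt JSON text produced by [params_to_json()].
#' @return `params_to_json()` returns a JSON string; `params_from_json()`
#'   returns a `ddm_params` object.
#' @export
params_to_json <- function(p) {
  validate_ddm_params(p)
  jsonlite::toJSON(unclass(p), auto_unbox = FALSE, digits = NA)
}

#' @rdname params_to_json
#' @export
params_from_json <- function(txt) {
  x <- jsonlite::fromJSON(txt)
  ddm_params(v = unlist(x$v), a = unlist(x$a), ter = unlist(x$ter),
             eta = unlist(x$eta), z = unlist(x$z), sz = unlist(x$sz),
             st = unlist(x$st), s = x$s, conditions = unlist(x$conditions))
}

# Gauss-Legendre nodes/weights on [-1, 1], used for the uniform sz and st
# integrals (11 nodes by default, see fit_options()).
gauss_legendre <- function(n) {
  if (n == 1L) return(list(x = 0, w = 2))
  g <- pracma::gaussLegendre(n, -1, 1)
  list(x = g$x, w = g$w)
}
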