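#' Constraint specification for the six DDM variants
#'
#' Declarative map of which parameters vary across the three task conditions
#' and how the starting point is treated:
#' * Model 1: drift rate `v` and drift variability `eta` free per condition;
#'   boundary `a`, start range `sz`, nondecision `ter` and its range `st`
#'   shared; start fixed at `a/2` (10 free parameters).
#' * Model 2: additionally `a` and `sz` free per condition (14).
#' * Model 3: additionally `ter` and `st` free per condition (18).
#' * Models 4-6: as 1-3 but with an estimated starting point, shared across
#'   conditions, that may differ from half the boundary separation
#'   (11/15/19 free parameters).
#'
#' @param id Model id, 1 to 6.
#' @param conditions Condition labels (default the three task conditions).
#' @return A `model_spec` list with `id`, `per_condition`, `bias`,
#'   `n_free`, `conditions`.
#' @export
model_spec <- function(id, conditions = ddm_conditions()) {
  id <- as.integer(id)
  stopifnot(id %in% 1:6)
  base <- ((id - 1L) %% 3L) + 1L
  per_condition <- switch(base,
                          c("v", "eta"),
                          c("v", "eta", "a", "sz"),
                          c("v", "eta", "a", "sz", "ter", "st"))
  bias <- id >= 4L
  nc <- length(conditions)
  all_pars <- c("v", "eta", "a", "sz", "ter", "st")
  n_free <- sum(ifelse(all_pars %in% per_condition, nc, 1L)) + as.integer(bias)
  structure(list(id = id, per_condition = per_condition, bias = bias,
                 n_free = n_free, conditions = conditions),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("Model %d: {%s} free across conditions; start %s; %d free parameters\n",
              x$id, paste(x$per_condition, collapse = ", "),
              if (x$bias) "estimated (shared)" else "fixed at a/2", x$n_free))
  invisible(x)
}

par_vector_names <- function(spec) {
  all_pars <- c("v", "eta", "a", "sz", "ter", "st")
  nm <- unlist(lapply(all_pars, function(p) {
    if (p %in% spec$per_condition) paste(p, spec$conditions, sep = ".") else p
  }))
  if (spec$bias) nm <- c(nm, "w")
  nm
}

#' Pack a full parameter set into a model's free-parameter vector
#'
#' `pack_parameters()` collapses a per-condition [ddm_params()] object to the
#' natural-scale free-parameter vector of a model (length `spec$n_free`);
#' shared parameters must be identical across conditions. The estimated
#' starting point of the biased models is packed as the relative bias
#' `w = z / min(a)`. `unpack_parameters()` is its exact inverse.
#'
#' @param spec A [model_spec()].
#' @param params A [ddm_params()] object consistent with `spec`.
#' @return A named numeric vector of length `spec$n_free`.
#' @export
pack_parameters <- function(spec, params) {
  validate_ddm_params(params)
  stopifnot(identical(params$conditions, spec$conditions))
  out <- c()
  for (p in c("v", "eta", "a", "sz", "ter", "st")) {
    x <- params[[p]]
    if (p %in% spec$per_condition) {
      out <- c(out, stats::setNames(x, paste(p, spec$conditions, sep = ".")))
    } else {
      if (diff(range(x)) > 1e-12) {
        stop(sprintf("`%s` is shared under Model %d but varies across conditions",
                     p, spec$id), call. = FALSE)
      }
      out <- c(out, stats::setNames(x[[1]], p))
    }
  }
  if (spec$bias) {
    out <- c(out, w = unname(params$z[[1]] / min(params$a)))
  }
  out
}

#' @rdname pack_parameters
#' @param vec Named or unnamed numeric vector of length `spec$n_free` on the
#'   natural scale (ordering of [pack_parameters()]).
#' @export
unpack_parameters <- function(spec, vec) {
  nm <- par_vector_names(spec)
  if (length(vec) != length(nm)) {
    stop(sprintf("parameter vector for Model %d must have length %d, got %d",
                 spec$id, length(nm), length(vec)), call. = FALSE)
  }
  vec <- stats::setNames(as.numeric(vec), nm)
  get_par <- function(p) {
    if (p %in% spec$per_condition) {
      stats::setNames(vec[paste(p, spec$conditions, sep = ".")],
                      spec$conditions)
    } else {
      rep(vec[[p]], length(spec$conditions))
    }
  }
  a <- get_par("a")
  z <- if (spec$bias) rep(vec[["w"]] * min(a), length(spec$conditions)) else a / 2
  ddm_params(v = get_par("v"), a = a, ter = get_par("ter"),
             eta = get_par("eta"), z = z, sz = get_par("sz"),
             st = get_par("st"), conditions = spec$conditions)
}

# ---- unconstrained transform for the simplex search -------------------------
#
# The optimizer works on an unconstrained vector theta; the mapping to the
# natural scale enforces every invariant by construction:
#   v           identity
#   eta         logistic * 0.5            (bounded: weakly identified)
#   a, ter      exp                        (positive)
#   w           logistic                   (0 < z < min(a))
#   sz          logistic * 0.9 * 2*min(z, a - z)   (start support inside (0,a))
#   st          logistic * 2 * ter         (ter - st/2 >= 0)

ETA_MAX <- 0.5
SZ_FRAC <- 0.9

logit_clamp <- function(p) stats::qlogis(pmin(pmax(p, 1e-9), 1 - 1e-9))

theta_to_params <- function(spec, theta) {
  nm <- par_vector_names(spec)
  stopifnot(length(theta) == length(nm))
  theta <- stats::setNames(as.numeric(theta), nm)
  nc <- length(spec$conditions)
  get_t <- function(p) {
    if (p %in% spec$per_condition) {
      unname(theta[paste(p, spec$conditions, sep = ".")])
    } else {
      rep(unname(theta[[p]]), nc)
    }
  }
  v <- get_t("v")
  eta <- stats::plogis(get_t("eta")) * ETA_MAX
  a <- exp(get_t("a"))
  ter <- exp(get_t("ter"))
  w <- if (spec$bias) stats::plogis(theta[["w"]]) else NA_real_
  z <- if (spec$bias) rep(w * min(a), nc) else a / 2
  half_gap <- pmin(z, a - z)
  sz_max <- SZ_FRAC * 2 * half_gap
  if (!("sz" %in% spec$per_condition)) sz_max <- rep(min(sz_max), nc)
  sz <- stats::plogis(get_t("sz")) * sz_max
  st <- stats::plogis(get_t("st")) * 2 * ter
  ddm_params(v = v, a = a, ter = ter, eta = eta, z = z, sz = sz, st = st,
             conditions = spec$conditions)
}

params_to_theta <- function(spec, params) {
  nat <- pack_parameters(spec, params)
  nm <- names(nat)
  theta <- nat
  z <- params$z
  a <- params$a
  half_gap <- pmin(z, a - z)
  sz_max_c <- SZ_FRAC * 2 * half_gap
  for (i in seq_along(nat)) {
    p <- sub("\\..*$", "", nm[i])
    theta[i] <- switch(
      p,
      v = nat[i],
      eta = logit_clamp(nat[i] / ETA_MAX),
      a = log(nat[i]),
      ter = log(nat[i]),
      w = logit_clamp(nat[i]),
      sz = {
        cap <- if ("sz" %in% spec$per_condition) {
          sz_max_c[[sub("^sz\\.", "", nm[i])]]
        } else {
          min(sz_max_c)
        }
        logit_clamp(nat[i] / cap)
      },
      st = {
        ter_i <- if ("st" %in% spec$per_condition) {
          params$ter[[sub("^st\\.", "", nm[i])]]
        } else {
          params$ter[[1]]
        }
        logit_clamp(nat[i] / (2 * ter_i))
      })
  }
  theta
}
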