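test_that("upper and lower defective densities integrate to one across the study's parameter scale", {
  grid <- expand.grid(v = c(0, 0.196, 0.366), a = c(0.176, 0.229))
  for (i in seq_len(nrow(grid))) {
    iu <- integrate_density(wfpt_density, boundary = "upper",
                            v = grid$v[i], a = grid$a[i])
    il <- integrate_density(wfpt_density, boundary = "lower",
                            v = grid$v[i], a = grid$a[i])
    expect_lt(abs(iu + il - 1), 1e-6)
  }
  # and with full intertrial variabilities
  p <- one_cond_params(v = 0.23, a = 0.2, ter = 0.35, eta = 0.12, sz = 0.05,
                       st = 0.12)
  iu <- integrate_density(function(t) full_density(t, "upper", p, "c"))
  il <- integrate_density(function(t) full_density(t, "lower", p, "c"))
  expect_lt(abs(iu + il - 1), 1e-6)
})

test_that("zero drift with central start splits mass evenly", {
  iu <- integrate_density(wfpt_density, boundary = "upper", v = 0, a = 0.15)
  expect_lt(abs(iu - 0.5), 1e-8)
  p <- one_cond_params(v = 0, a = 0.15, ter = 0.3)
  expect_equal(choice_probability(p, "c"), 0.5, tolerance = 1e-8)
})

test_that("density integral matches the closed-form absorption probability", {
  # at the published young positive-drift parameters the upper boundary
  # absorbs ~0.998 of the mass
  v <- 0.366; a <- 0.176; s <- 0.1
  closed <- 1 / (1 + exp(-v * a / s^2))
  expect_equal(closed, 0.998, tolerance = 5e-4)
  iu <- integrate_density(wfpt_density, boundary = "upper", v = v, a = a)
  expect_lt(abs(iu - closed), 1e-7)
  # biased start, generic formula (e^{-2vz/s^2}-1)/(e^{-2va/s^2}-1)
  z <- 0.05
  closed_z <- expm1(-2 * v * z / s^2) / expm1(-2 * v * a / s^2)
  iz <- integrate_density(wfpt_density, boundary = "upper", v = v, a = a,
                          z = z)
  expect_lt(abs(iz - closed_z), 1e-7)
})

test_that("negating the drift and reflecting the start swaps the boundaries exactly", {
  t <- seq(0.01, 2, length.out = 80)
  for (pars in list(c(v = 0.3, a = 0.18, z = 0.06),
                    c(v = -0.15, a = 0.22, z = 0.15))) {
    up <- wfpt_density(t, "upper", v = pars["v"], a = pars["a"], z = pars["z"])
    lo <- wfpt_density(t, "lower", v = -pars["v"], a = pars["a"],
                       z = pars["a"] - pars["z"])
    # identical up to the rounding of the reflected relative start
    expect_equal(up, lo, tolerance = 1e-12)
  }
})

test_that("full density reduces exactly to the plain density at degenerate variabilities", {
  t <- seq(0.35, 3, by = 0.05)
  p <- one_cond_params(v = 0.25, a = 0.2, ter = 0.3)
  expect_identical(full_density(t, "upper", p, "c"),
                   wfpt_density(t - 0.3, "upper", v = 0.25, a = 0.2))
  expect_identical(full_density(t, "lower", p, "c"),
                   wfpt_density(t - 0.3, "lower", v = 0.25, a = 0.2))
})

test_that("analytic drift-variability integration matches adaptive quadrature to 1e-6 relative", {
  p <- one_cond_params(v = 0.3, a = 0.18, ter = 0.3, eta = 0.12)
  t <- c(0.4, 0.5, 0.7, 1.0, 1.6)
  for (resp in c("upper", "lower")) {
    got <- full_density(t, resp, p, "c")
    oracle <- vapply(t, function(tt) {
      stats::integrate(function(u) {
        vapply(u, function(uu) {
          wfpt_density(tt - 0.3, resp, v = uu, a = 0.18)
        }, 0) * stats::dnorm(u, 0.3, 0.12)
      }, 0.3 - 10 * 0.12, 0.3 + 10 * 0.12, rel.tol = 1e-12)$value
    }, 0)
    expect_lt(max(abs(got - oracle) / oracle), 1e-6)
  }
})

test_that("starting-point and nondecision variability quadrature matches an adaptive oracle", {
  p <- one_cond_params(v = 0.25, a = 0.2, ter = 0.35, sz = 0.06, st = 0.15)
  t <- c(0.45, 0.6, 0.8, 1.2)
  got <- full_density(t, "upper", p, "c", n_quad = 11)
  oracle <- vapply(t, function(tt) {
    stats::integrate(function(z0) {
      vapply(z0, function(zz) {
        stats::integrate(function(t0) {
          vapply(t0, function(t00) {
            td <- tt - t00
            if (td <= 0) 0 else wfpt_density(td, "upper", v = 0.25, a = 0.2,
                                             z = zz)
          }, 0) / 0.15
        }, 0.35 - 0.075, 0.35 + 0.075, rel.tol = 1e-10)$value / 0.06
      }, 0)
    }, 0.1 - 0.03, 0.1 + 0.03, rel.tol = 1e-10)$value
  }, 0)
  expect_lt(max(abs(got - oracle) / oracle), 1e-5)
})

test_that("choice probabilities are coherent, normalized, and ordered in drift and caution", {
  p <- one_cond_params(v = 0.3, a = 0.18, ter = 0.3, eta = 0.12, sz = 0.04)
  pu <- choice_probability(p, "c")
  pm <- one_cond_params(v = -0.3, a = 0.18, ter = 0.3, eta = 0.12, sz = 0.04)
  pl <- 1 - choice_probability(pm, "c")
  expect_lt(abs(pu - pl), 1e-8)
  expect_gt(pu, 0); expect_lt(pu, 1)
  # increasing in v
  pv <- vapply(c(0.1, 0.2, 0.3), function(v) {
    choice_probability(one_cond_params(v = v, a = 0.18, ter = 0.3), "c")
  }, 0)
  expect_true(all(diff(pv) > 0))
  # increasing in a for v > 0 with central start
  pa <- vapply(c(0.12, 0.18, 0.24), function(a) {
    choice_probability(one_cond_params(v = 0.2, a = a, ter = 0.3), "c")
  }, 0)
  expect_true(all(diff(pa) > 0))
})

test_that("choice probability matches simulated accuracy at the published parameter scale", {
  p <- young_params()
  pu <- choice_probability(p, "positive")
  sim <- simulate_condition(p, "positive", 30000, sim_options(seed = 31))
  expect_lt(abs(pu - mean(sim$accuracy)), 0.01)
})

test_that("predicted quantiles invert the defective CDF and respond to caution", {
  p <- one_cond_params(v = 0.25, a = 0.18, ter = 0.3)
  q <- predicted_quantiles(p, "c")
  expect_identical(q$response, c("correct", "error"))
  expect_lt(abs(sum(q$prop) - 1), 1e-3)
  qc <- unlist(q[q$response == "correct", paste0("q", c(10, 30, 50, 70, 90))])
  expect_true(all(diff(qc) > 0))
  # median definition: CDF at q50 equals half the response probability
  g <- piddm:::defective_cdf_grid(p, "c", "upper")
  cdf_at <- stats::approx(g$t, g$cdf, xout = qc[3])$y
  expect_equal(cdf_at, 0.5 * q$prop[q$response == "correct"],
               tolerance = 1e-3)
  # raising the boundary (central start maintained) slows every quantile
  q_wide <- predicted_quantiles(one_cond_params(v = 0.25, a = 0.26,
                                                ter = 0.3), "c")
  qw <- unlist(q_wide[q_wide$response == "correct",
                          paste0("q", c(10, 30, 50, 70, 90))])
  expect_true(all(qw > qc))
})

test_that("predicted quantiles track empirical quantiles of the simulator", {
  p <- one_cond_params(v = 0.25, a = 0.18, ter = 0.33, eta = 0.1, sz = 0.03,
                       st = 0.1)
  q <- predicted_quantiles(p, "c")
  sim <- simulate_condition(p, "c", 40000, sim_options(seed = 77))
  rt_c <- sim$rt_s[sim$accuracy == 1]
  emp <- stats::quantile(rt_c, c(.1, .3, .5, .7, .9), type = 7, names = FALSE)
  pred <- unlist(q[q$response == "correct",
                       paste0("q", c(10, 30, 50, 70, 90))])
  expect_lt(max(abs(pred - emp)), 0.015)
  expect_lt(abs(q$prop[q$response == "correct"] - mean(sim$accuracy)), 0.01)
})

test_that("sparse-response cells are flagged rather than fabricated", {
  # enormous drift: errors are essentially impossible
  p <- one_cond_params(v = 3, a = 0.2, ter = 0.3)
  q <- predicted_quantiles(p, "c")
  err <- q[q$response == "error", ]
  expect_false(err$reliable)
  expect_true(all(is.na(err[paste0("q", c(10, 30, 50, 70, 90))])))
})

test_that("invalid density inputs fail loudly", {
  expect_error(wfpt_density(c(0.1, -0.2), "upper", v = 0.3, a = 0.18),
               "finite and > 0")
  expect_error(ddm_params(v = 0.3, a = -1, ter = 0.3), "boundary separation")
  expect_error(ddm_params(v = 0.3, a = 0.2, ter = 0.3, z = 0.25), "0 < z < a")
  expect_error(ddm_params(v = 0.3, a = 0.2, ter = 0.05, st = 0.2),
               "ter - st/2")
})
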