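test_that("RT cutoffs exclude exactly the planted outliers", {
  set.seed(3)
  d <- tibble::tibble(rt_s = c(runif(997, 0.3, 2.0),
                               0.15, 0.05, 7.5))  # three planted outliers
  res <- apply_rt_cutoffs(d)
  expect_equal(res$excluded_fraction, 0.003)
  expect_equal(res$n_excluded, 3)
  expect_true(all(res$data$rt_s >= 0.2 & res$data$rt_s <= 7))

  clean <- tibble::tibble(rt_s = runif(100, 0.3, 2.0))
  expect_equal(apply_rt_cutoffs(clean)$excluded_fraction, 0)
  expect_error(apply_rt_cutoffs(tibble::tibble(rt_s = c(0.05, 8),
                                               participant_id = "p9")),
               "p9")
})

test_that("model constraint maps have the documented free-parameter counts", {
  expect_equal(vapply(1:6, function(m) model_spec(m)$n_free, 0L),
               c(10L, 14L, 18L, 11L, 15L, 19L))
  for (m in 1:6) {
    spec <- model_spec(m)
    p <- young_params()
    if (spec$bias) {
      p <- ddm_params(v = p$v, a = p$a, ter = p$ter, eta = p$eta,
                      z = 0.45 * p$a, sz = p$sz, st = p$st)
    }
    vec <- pack_parameters(spec, p)
    expect_length(vec, spec$n_free)
  }
})

test_that("pack/unpack round-trips random valid parameter sets for all six models", {
  set.seed(42)
  for (m in 1:6) {
    spec <- model_spec(m)
    for (rep in 1:5) {
      per <- function(shared) if (shared) rep(runif(1, 0.1, 0.3), 3) else runif(3, 0.1, 0.3)
      a <- per(!("a" %in% spec$per_condition))
      ter <- per(!("ter" %in% spec$per_condition)) + 0.2
      z <- if (spec$bias) rep(runif(1, 0.3, 0.7) * min(a), 3) else a / 2
      szc <- if ("sz" %in% spec$per_condition) {
        pmin(z, a - z) * runif(3, 0.1, 0.8)
      } else {
        rep(min(pmin(z, a - z)) * runif(1, 0.1, 0.8), 3)
      }
      stc <- if ("st" %in% spec$per_condition) {
        ter * runif(3, 0.1, 0.8)
      } else {
        rep(min(ter) * runif(1, 0.1, 0.8), 3)
      }
      p <- ddm_params(v = runif(3, -0.2, 0.4), a = a, ter = ter,
                      eta = runif(3, 0, 0.3), z = z, sz = szc, st = stc)
      vec <- pack_parameters(spec, p)
      p2 <- unpack_parameters(spec, vec)
      expect_equal(p2, p, tolerance = 1e-12)
      expect_equal(pack_parameters(spec, p2), vec, tolerance = 1e-12)
    }
  }
  expect_error(unpack_parameters(model_spec(1), rep(0.1, 9)), "length 10")
})

test_that("the unconstrained transform can never propose an invalid parameter set", {
  set.seed(7)
  for (m in 1:6) {
    spec <- model_spec(m)
    for (rep in 1:20) {
      theta <- rnorm(spec$n_free, 0, 3)
      p <- piddm:::theta_to_params(spec, theta)
      expect_silent(validate_ddm_params(p))
      # and the inverse transform recovers theta through the parameters
      p2 <- piddm:::theta_to_params(spec, piddm:::params_to_theta(spec, p))
      expect_equal(p2, p, tolerance = 1e-6)
    }
  }
})

test_that("moment-based initialization points in the right direction and stays finite", {
  d <- simulated_participant(seed = 31)
  for (m in c(1, 4)) {
    spec <- model_spec(m)
    init <- initialize_parameters(d, spec)
    expect_silent(validate_ddm_params(init))
    expect_true(all(init$v > 0))  # simulated drifts are all positive
    ll <- log_likelihood(d, init, spec, n_quad = 5)
    expect_true(is.finite(ll))
  }
  # strongly negative drift flips the initial sign
  pneg <- one_cond_params(v = -0.35, a = 0.18, ter = 0.3)
  sim <- simulate_condition(pneg, "c", 300, sim_options(seed = 13))
  dneg <- tibble::tibble(condition = "c", rt_s = sim$rt_s,
                         accuracy = sim$accuracy)
  ez <- piddm:::ez_condition(dneg$accuracy, dneg$rt_s[dneg$accuracy == 1],
                             0.1, nrow(dneg))
  expect_lt(ez$v, 0)
})

test_that("perfect accuracy is clamped by the edge-correction rule", {
  set.seed(8)
  rts <- runif(100, 0.4, 0.9)
  got <- piddm:::ez_condition(rep(1, 100), rts, 0.1, 100)
  # oracle: EZ closed form evaluated at the clamped accuracy 1 - 1/(2*100)
  pc <- 0.995
  L <- qlogis(pc)
  x <- L * (L * pc^2 - L * pc + pc - 0.5) / var(rts)
  v <- 0.1 * x^(1 / 4)
  expect_equal(got$v, v, tolerance = 1e-12)
  expect_equal(got$a, 0.01 * L / v, tolerance = 1e-12)
})

test_that("log-likelihood is additive over trials", {
  d <- simulated_participant(seed = 17, design = small_design())
  spec <- model_spec(1)
  p <- young_params()
  ll1 <- log_likelihood(d, p, spec, n_quad = 5)
  ll2 <- log_likelihood(dplyr::bind_rows(d, d), p, spec, n_quad = 5)
  expect_equal(ll2, 2 * ll1, tolerance = 1e-10)
})

test_that("the generating parameters dominate perturbed ones in likelihood at large n", {
  d <- simulated_participant(seed = 23)
  spec <- model_spec(1)
  truth <- young_params()
  worse <- ddm_params(v = truth$v * 2, a = truth$a, ter = truth$ter,
                      eta = truth$eta, sz = truth$sz, st = truth$st)
  expect_gt(log_likelihood(d, truth, spec, n_quad = 5),
            log_likelihood(d, worse, spec, n_quad = 5))
})

test_that("fitting is deterministic and improves on its initialization", {
  d <- simulated_participant(seed = 29, design = small_design())
  spec <- model_spec(1)
  opts <- fast_fit(seed = 3, n_quad = 3, maxit = 400, n_restarts = 2)
  f1 <- suppressWarnings(fit_participant(d, spec, opts, "p1"))
  f2 <- suppressWarnings(fit_participant(d, spec, opts, "p1"))
  expect_identical(f1$params, f2$params)
  expect_identical(f1$log_likelihood, f2$log_likelihood)
  expect_gte(f1$log_likelihood,
             log_likelihood(d, f1$init, spec, n_quad = 3))
  expect_equal(f1$bic, -2 * f1$log_likelihood + spec$n_free * log(nrow(d)))
})

test_that("Model 1 refits recover the generating parameters from one session", {
  d <- simulated_participant(seed = 37)
  f <- fit_participant(d, model_spec(1), fast_fit(seed = 2), "p1")
  expect_true(f$converged)
  truth <- young_params()
  expect_lt(abs(f$params$v[["positive"]] - truth$v[["positive"]]), 0.08)
  expect_lt(abs(f$params$a[[1]] - truth$a[[1]]), 0.03)
  expect_lt(abs(f$params$ter[[1]] - truth$ter[[1]]), 0.04)
  # drift ordering across conditions is preserved
  expect_gt(f$params$v[["positive"]], f$params$v[["recent_negative"]])
})
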