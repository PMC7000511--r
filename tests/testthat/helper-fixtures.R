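# Shared fixtures: everything is generated in code at test time.

# A Model-1-style parameter set at the published young-adult scale.
young_params <- function() reference_group_params("young")$means

# Single-condition parameter set for density-level tests.
one_cond_params <- function(v = 0.3, a = 0.18, ter = 0.3, eta = 0, z = NULL,
                            sz = 0, st = 0) {
  ddm_params(v = v, a = a, ter = ter, eta = eta, z = z, sz = sz, st = st,
             conditions = "c")
}

# Small session (1 block x 40 trials: 20/10/10) for fast end-to-end paths.
small_design <- function() session_design(n_blocks = 1L, trials_per_block = 40L)

# One participant's post-cutoff dataset simulated at the young means.
simulated_participant <- function(seed = 11, design = session_design(),
                                  params = young_params(), id = "p1") {
  trials <- generate_session(design, seed = seed)
  d <- simulate_dataset(params, trials, sim_options(seed = seed + 1))
  d$participant_id <- id
  d$group <- "young"
  apply_rt_cutoffs(d)$data
}

# Fast fitting options for tests: single restart from the moment-based start,
# 5-node quadrature (log-lik within ~0.001 of the 21-node value at this
# parameter scale), generous iteration cap.
fast_fit <- function(seed = 1, n_quad = 5L, n_restarts = 1L, maxit = 3000L) {
  fit_options(n_restarts = n_restarts, seed = seed, n_quad = n_quad,
              maxit = maxit)
}

# Numeric integral of a defective density over (0, upper).
integrate_density <- function(f, upper = Inf, ...) {
  stats::integrate(f, 0, upper, ..., rel.tol = 1e-9,
                   subdivisions = 500L)$value
}
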