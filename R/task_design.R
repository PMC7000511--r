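#' Recent-probes session design
#'
#' Describes one session of the recent-probes task: participants memorize a
#' target set of four lowercase consonants and, after a delay, judge whether
#' a probe consonant belongs to it. Half of the probes are positive; negative
#' probes are split between non-recent negatives (absent from the current and
#' the two preceding target sets) and recent negatives (absent from the
#' current set but present in the immediately preceding one, the condition
#' that induces proactive interference).
#'
#' @param n_blocks Number of blocks (default 3).
#' @param trials_per_block Trials per block (default 160).
#' @param n_targets Target-set size (default 4).
#' @param stimulus_pool Lowercase consonants to draw from (default all 20).
#' @param proportions Named condition proportions summing to 1.
#' @param timing Nominal event durations in ms (recorded; not simulated).
#' @return A `session_design` list.
#' @export
session_design <- function(n_blocks = 3L, trials_per_block = 160L,
                           n_targets = 4L,
                           stimulus_pool = setdiff(letters, c("a", "e", "i",
                                                              "o", "u", "y")),
                           proportions = c(positive = 0.5,
                                           nonrecent_negative = 0.25,
                                           recent_negative = 0.25),
                           timing = c(fixation_ms = 500, target_ms = 1500,
                                      delay_ms = 3000, intertrial_ms = 1000)) {
  stopifnot(n_blocks >= 1, trials_per_block >= 1, n_targets >= 1)
  if (abs(sum(proportions) - 1) > 1e-12) {
    stop("condition proportions must sum to 1", call. = FALSE)
  }
  if (is.null(names(proportions)) ||
      !all(names(proportions) %in% ddm_conditions())) {
    stop("proportions must be named with the task conditions", call. = FALSE)
  }
  structure(list(n_blocks = as.integer(n_blocks),
                 trials_per_block = as.integer(trials_per_block),
                 n_targets = as.integer(n_targets),
                 stimulus_pool = stimulus_pool,
                 proportions = proportions, timing = timing),
            class = "session_design")
}

#' Generate one session of recent-probes trials
#'
#' Produces the full trial sequence for a session with exact per-session
#' condition counts (e.g. 240 positive / 120 non-recent negative / 120 recent
#' negative for the default 3 x 160 design) and all recency constraints
#' satisfied: recent-negative probes come from the immediately preceding
#' target set, non-recent negative probes avoid the two preceding sets.
#' Because the recency look-back is undefined at the start of a session, the
#' first two trials are drawn from the positive / non-recent conditions only
#' (recent negatives are placed from trial 3 on); counts are balanced over
#' the remainder so session totals are exact.
#'
#' @param design A [session_design()].
#' @param seed Integer seed; the sequence is deterministic given the seed.
#' @return A tibble with columns `trial`, `block`, `target_set` (the set as a
#'   single string), `probe`, `condition`, `correct_response`.
#' @export
generate_session <- function(design = session_design(), seed = 1L) {
  pool <- design$stimulus_pool
  nt <- design$n_targets
  has_negatives <- any(design$proportions[setdiff(names(design$proportions),
                                                  "positive")] > 0)
  if (has_negatives && length(pool) < 3 * nt + 1) {
    stop(sprintf(paste0("stimulus pool too small: non-recent negatives need ",
                        "more than 3 x %d distinct stimuli, got %d"),
                 nt, length(pool)), call. = FALSE)
  }
  n <- design$n_blocks * design$trials_per_block
  counts <- round(design$proportions * n)
  if (sum(counts) != n) {
    stop("condition proportions do not yield integer trial counts",
         call. = FALSE)
  }

  set.seed(seed)
  conds <- sample(rep(names(counts), counts))
  # burn-in: the first two trials must not be recent negatives
  burn <- min(2L, n)
  for (i in seq_len(burn)) {
    if (conds[i] == "recent_negative") {
      cand <- which(conds[-seq_len(burn)] != "recent_negative") + burn
      if (length(cand) == 0) {
        stop("cannot place recent negatives: design leaves no room after the ",
             "two-trial burn-in", call. = FALSE)
      }
      j <- cand[sample.int(length(cand), 1)]
      tmp <- conds[i]; conds[i] <- conds[j]; conds[j] <- tmp
    }
  }

  target_sets <- vector("list", n)
  probes <- character(n)
  for (i in seq_len(n)) {
    repeat {
      ts <- sample(pool, nt)
      # a recent negative on the next trial needs this set to leave something
      # of the current set available; identical consecutive sets would not
      if (i == 1 || length(setdiff(target_sets[[i - 1]], ts)) > 0) break
    }
    target_sets[[i]] <- ts
    probes[i] <- switch(
      conds[i],
      positive = sample(ts, 1),
      recent_negative = {
        cand <- setdiff(target_sets[[i - 1]], ts)
        cand[sample.int(length(cand), 1)]
      },
      nonrecent_negative = {
        prev <- unlist(target_sets[max(1, i - 2):max(1, i - 1)][
          seq_len(min(2, i - 1))])
        cand <- setdiff(pool, c(ts, prev))
        if (length(cand) == 0) {
          stop("stimulus pool exhausted for a non-recent negative probe",
               call. = FALSE)
        }
        cand[sample.int(length(cand), 1)]
      })
  }

  tibble::tibble(
    trial = seq_len(n),
    block = rep(seq_len(design$n_blocks), each = design$trials_per_block),
    target_set = vapply(target_sets, paste, "", collapse = ""),
    probe = probes,
    condition = conds,
    correct_response = ifelse(conds == "positive", "positive", "negative"))
}

#' Check a trial sequence against the recency constraints
#'
#' Re-derives, for every trial, whether its probe is consistent with its
#' condition label given the current and the two preceding target sets.
#' Reports; never mutates.
#'
#' @param trials A trial tibble as returned by [generate_session()].
#' @return A list with `per_trial` (tibble: trial, condition, ok, reason),
#'   `n_violations`, and `condition_counts`.
#' @export
validate_sequence <- function(trials) {
  stopifnot(nrow(trials) > 0)
  sets <- strsplit(trials$target_set, "")
  n <- nrow(trials)
  ok <- logical(n)
  reason <- character(n)
  for (i in seq_len(n)) {
    cur <- sets[[i]]
    prev1 <- if (i >= 2) sets[[i - 1]] else character(0)
    prev2 <- if (i >= 3) sets[[i - 2]] else character(0)
    pr <- trials$probe[i]
    res <- switch(
      trials$condition[i],
      positive = if (pr %in% cur) "" else "positive probe not in target set",
      recent_negative =
        if (pr %in% cur) "recent negative probe in current target set"
        else if (i == 1) "recent negative has no preceding trial"
        else if (!pr %in% prev1) "recent negative probe not in preceding set"
        else "",
      nonrecent_negative =
        if (pr %in% cur) "non-recent negative probe in current target set"
        else if (pr %in% c(prev1, prev2))
          "non-recent negative probe in a recent target set"
        else "",
      sprintf("unknown condition '%s'", trials$condition[i]))
    ok[i] <- res == ""
    reason[i] <- res
  }
  list(per_trial = tibble::tibble(trial = trials$trial,
                                  condition = trials$condition,
                                  ok = ok, reason = reason),
       n_violations = sum(!ok),
       condition_counts = table(trials$condition))
}

#' Reference group-level DDM parameters for the recent-probes task
#'
#' Published group means and standard errors of the winning model's
#' parameters (drift rate per condition, boundary separation, nondecision
#' time) for young (n = 25) and older (n = 38) adults. These are the default
#' generating values for synthetic cohorts. Between-subject SDs are derived
#' as `SE * sqrt(n)`. The intertrial variabilities, for which no group values
#' are published, default to `eta = 0.10` per condition, `sz = 0.02`,
#' `st = 0.10` s.
#'
#' @param group `"young"` or `"older"`.
#' @return A list with `label`, `n`, `means` (a [ddm_params()]), `se`, and
#'   `sds` (between-subject SDs; zero for the variability parameters).
#' @export
reference_group_params <- function(group = c("young", "older")) {
  group <- match.arg(group)
  tab <- list(
    young = list(n = 25,
                 v = c(positive = 0.366, nonrecent_negative = 0.290,
                       recent_negative = 0.230),
                 v_se = c(0.025, 0.017, 0.014), a = 0.176, a_se = 0.010,
                 ter = 0.304, ter_se = 0.011),
    older = list(n = 38,
                 v = c(positive = 0.304, nonrecent_negative = 0.255,
                       recent_negative = 0.196),
                 v_se = c(0.020, 0.014, 0.011), a = 0.229, a_se = 0.007,
                 ter = 0.455, ter_se = 0.023))
  g <- tab[[group]]
  rt_n <- sqrt(g$n)
  list(label = group, n = g$n,
       means = ddm_params(v = g$v, a = g$a, ter = g$ter,
                          eta = 0.10, sz = 0.02, st = 0.10),
       se = list(v = stats::setNames(g$v_se, names(g$v)), a = g$a_se,
                 ter = g$ter_se),
       sds = list(v = stats::setNames(g$v_se * rt_n, names(g$v)),
                  a = g$a_se * rt_n, ter = g$ter_se * rt_n))
}

#' Cohort specification
#'
#' @param groups A list of group specifications, each a list with `label`,
#'   `n` (participants), `means` (a [ddm_params()]), and `sds` (a list with
#'   per-condition `v` and scalar `a`, `ter` between-subject SDs; zero SDs
#'   give identical participants).
#' @param seed Integer seed for participant-level sampling.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(groups, seed = 1L) {
  for (g in groups) {
    stopifnot(!is.null(g$label), g$n > 0, inherits(g$means, "ddm_params"))
    sds <- unlist(g$sds)
    if (any(sds < 0)) stop("between-subject SDs must be >= 0", call. = FALSE)
    validate_ddm_params(g$means)
  }
  structure(list(groups = groups, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Default two-group cohort at the published parameter scale
#'
#' Convenience wrapper building a [cohort_spec()] with the young and older
#' reference means; `between_sd = FALSE` sets all between-subject SDs to
#' zero (every participant exactly at the group means).
#'
#' @param n_young,n_older Participants per group.
#' @param seed Sampling seed.
#' @param between_sd Use the `SE * sqrt(n)`-derived between-subject SDs.
#' @return A [cohort_spec()].
#' @export
default_cohort_spec <- function(n_young = 25L, n_older = 38L, seed = 1L,
                                between_sd = TRUE) {
  mk <- function(group, n) {
    ref <- reference_group_params(group)
    sds <- if (between_sd) ref$sds else list(v = ref$sds$v * 0, a = 0, ter = 0)
    list(label = group, n = n, means = ref$means, sds = sds)
  }
  cohort_spec(list(mk("young", n_young), mk("older", n_older)), seed = seed)
}

#' Sample participant-level parameter sets for a cohort
#'
#' Draws each participant's drift rates, boundary separation and nondecision
#' time from normal distributions around the group means with the
#' between-subject SDs, resampling any draw that violates the parameter
#' invariants (boundaries positive, starting-point and nondecision supports
#' valid). Intertrial variabilities are taken from the group means without
#' between-subject variation. Deterministic given the cohort seed.
#'
#' @param spec A [cohort_spec()].
#' @return A tibble with `participant_id`, `group`, and a `params`
#'   list-column of [ddm_params()] objects.
#' @export
sample_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  rows <- list()
  pid <- 0L
  for (g in spec$groups) {
    m <- g$means
    for (i in seq_len(g$n)) {
      pid <- pid + 1L
      repeat {
        v <- stats::rnorm(length(m$v), m$v, unlist(g$sds$v))
        a <- stats::rnorm(1, m$a[1], g$sds$a %||% 0)
        ter <- stats::rnorm(1, m$ter[1], g$sds$ter %||% 0)
        # resample-on-violation truncation at the parameter bounds
        if (a > max(2 * m$sz[1], 1e-3) && ter >= m$st[1] / 2) break
      }
      p <- ddm_params(v = stats::setNames(v, m$conditions), a = a, ter = ter,
                      eta = m$eta, sz = m$sz, st = m$st, s = m$s,
                      conditions = m$conditions)
      rows[[pid]] <- tibble::tibble(
        participant_id = sprintf("%s_%02d", g$label, i),
        group = g$label, params = list(p))
    }
  }
  dplyr::bind_rows(rows)
}

#' Synthesize a full behavioral dataset
#'
#' Generates a fresh trial sequence per participant and simulates every trial
#' from that participant's DDM parameters (stimulus-coded: the upper boundary
#' is the "positive" response; negative conditions drift toward the lower
#' boundary). The RT scale is seconds throughout.
#'
#' @param cohort Tibble from [sample_cohort()].
#' @param design A [session_design()].
#' @param seed Integer master seed; per-participant seeds are derived from it.
#' @param options Simulator options from [sim_options()].
#' @return A behavioral tibble: `participant_id`, `group`, `block`, `trial`,
#'   `condition`, `response`, `rt_s`, `accuracy`.
#' @export
synthesize_dataset <- function(cohort, design = session_design(), seed = 1L,
                               options = sim_options()) {
  out <- vector("list", nrow(cohort))
  for (i in seq_len(nrow(cohort))) {
    sub_seed <- as.integer((as.numeric(seed) * 10007 + i * 193) %%
                             .Machine$integer.max)
    trials <- generate_session(design, seed = sub_seed)
    opts <- options
    opts$seed <- as.integer((sub_seed + 1) %% .Machine$integer.max)
    sim <- simulate_dataset(cohort$params[[i]], trials, opts)
    sim$participant_id <- cohort$participant_id[i]
    sim$group <- cohort$group[i]
    out[[i]] <- sim[, c("participant_id", "group", "block", "trial",
                        "condition", "response", "rt_s", "accuracy")]
  }
  dplyr::bind_rows(out)
}

#' Read / write behavioral tables
#'
#' CSV with the canonical header: participant_id, group, block, trial,
#' condition, response, rt_s, accuracy; RTs in seconds.
#'
#' @param data Behavioral tibble.
#' @param path File path.
#' @return `read_behavior()` returns the tibble; `write_behavior()` the path,
#'   invisibly.
#' @export
write_behavior <- function(data, path) {
  utils::write.csv(data, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_behavior
#' @export
read_behavior <- function(path) {
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}
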