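#' Bayesian information criterion
#'
#' `-2 log L + k log n`; lower is better. With `n = 1` the penalty vanishes
#' (`log 1 = 0`).
#'
#' @param log_likelihood Fitted log-likelihood.
#' @param k Number of free parameters (> 0).
#' @param n Number of observations fitted (> 0).
#' @return Scalar BIC.
#' @examples
#' bic(-100, 10, 480) # 200 + 10 * log(480)
#' @export
bic <- function(log_likelihood, k, n) {
  stopifnot(n > 0, k > 0)
  -2 * log_likelihood + k * log(n)
}

#' Per-participant best model by BIC
#'
#' For each participant, the converged fit with the lowest BIC wins; exact
#' ties are broken toward fewer free parameters, then toward the lower model
#' id (a message is emitted whenever the tie rule decides). Participants
#' without any converged fit are excluded and reported.
#'
#' @param fits Fit tibble from [fit_models()] (columns `participant_id`,
#'   `model_id`, `n_free`, `bic`, `converged`).
#' @param tie_tol Absolute BIC difference treated as an exact tie.
#' @return A tibble of winners: `participant_id`, `group` (if present),
#'   `model_id`, `bic`; excluded participants in attribute `excluded`.
#' @export
select_best <- function(fits, tie_tol = 1e-8) {
  stopifnot(all(c("participant_id", "model_id", "n_free", "bic",
                  "converged") %in% names(fits)))
  winners <- list()
  excluded <- character(0)
  for (pid in unique(fits$participant_id)) {
    f <- fits[fits$participant_id == pid & fits$converged, , drop = FALSE]
    if (nrow(f) == 0) {
      excluded <- c(excluded, pid)
      message("participant ", pid,
              " excluded from ranking: no converged fit")
      next
    }
    tied <- f[f$bic <= min(f$bic) + tie_tol, , drop = FALSE]
    if (nrow(tied) > 1) {
      message("BIC tie for participant ", pid, " among models ",
              paste(tied$model_id, collapse = ", "),
              "; breaking toward parsimony then lower id")
      tied <- tied[order(tied$n_free, tied$model_id), , drop = FALSE]
    }
    w <- tied[1, , drop = FALSE]
    keep <- intersect(c("participant_id", "group", "model_id", "bic"),
                      names(w))
    winners[[length(winners) + 1L]] <- w[, keep, drop = FALSE]
  }
  out <- dplyr::bind_rows(winners)
  attr(out, "excluded") <- excluded
  out
}

#' Cohort-level model ranking
#'
#' Counts, per candidate model, how many participants it won and the
#' percentage of ranked participants, and ranks models by wins (rank 1 = most
#' wins). Percentages sum to 100 across models.
#'
#' @param winners Winner tibble from [select_best()].
#' @param models Candidate model ids to report (default those present).
#' @return A tibble: `model_id`, `n_best`, `percentage`, `rank`.
#' @export
ranking_table <- function(winners, models = sort(unique(winners$model_id))) {
  n_total <- nrow(winners)
  stopifnot(n_total > 0)
  counts <- vapply(models, function(m) sum(winners$model_id == m), 0L)
  out <- tibble::tibble(model_id = as.integer(models), n_best = counts,
                        percentage = 100 * counts / n_total)
  out$rank <- as.integer(rank(-out$n_best, ties.method = "min"))
  out[order(out$rank, out$model_id), ]
}
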