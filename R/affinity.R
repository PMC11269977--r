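#' Reference log-likelihood for relative-KD estimation
#'
#' The closed-form log-likelihood of the library under the reference model:
#' a uniform PWM of length `lw_ref` with no unspecific binding. Only window
#' counts and priors survive in the ratio, so no PWM evaluation is needed:
#' each read contributes `n_S * log[f_S (L_S - lw_ref + 1) /
#' sum_sigma f_sigma (L_sigma - lw_ref + 1)]`.
#'
#' @param library an annotated `read_library` with all reads at least
#'   `lw_ref` long.
#' @param lw_ref reference motif length (default 5, a typical RBP site).
#' @return the reference log-likelihood.
#' @export
reference_loglik <- function(library, lw_ref = 5) {
  assert_library(library, annotated = TRUE)
  if (any(nchar(library$seq) < lw_ref))
    abort("all reads must be at least lw_ref long")
  log_num <- library$log_prior + log(nchar(library$seq) - lw_ref + 1)
  sum(library$count * log_num) -
    sum(library$count) * logsumexp(log_num)
}

#' Relative dissociation constant of a fitted model
#'
#' Converts a fitted log-likelihood into the natural log of the dissociation
#' constant relative to the uniform length-`lw_ref` reference motif without
#' unspecific binding: per-read average of the likelihood gap plus a window
#' -count correction for the differing motif lengths,
#' `[logP_ref - logP_fit + sum_S n_S log((L_S - Lw + 1)/(L_S - lw_ref + 1))]
#'  / sum_S n_S`.
#' Lower values mean higher affinity; the estimate is invariant to uniform
#' scaling of the copy numbers and of the priors, so motifs of different
#' lengths fitted on the same library are directly comparable.
#'
#' @param fit an `em_fit` (should be convergent; a warning is issued
#'   otherwise).
#' @param library the annotated `read_library` the model was fitted on.
#' @param lw_ref reference motif length.
#' @return a one-row `kd_estimate` tibble: `log_kd_rel`, `lw`, `lw_ref`,
#'   `final_loglik`, `reference_loglik`, `consensus`.
#' @export
log_relative_kd <- function(fit, library, lw_ref = 5) {
  stopifnot(inherits(fit, "em_fit"))
  assert_library(library, annotated = TRUE)
  lw <- fit$lw
  keep <- nchar(library$seq) >= lw
  library <- library[keep, ]
  if (sum(library$count) != fit$n_reads)
    abort("library does not match the one fitted (read totals differ)")
  if (!fit$convergent)
    warn("relative KD computed for a non-convergent run")
  ref <- reference_loglik(library, lw_ref = lw_ref)
  n_tot <- sum(library$count)
  len_corr <- sum(library$count *
                    log((nchar(library$seq) - lw + 1) /
                          (nchar(library$seq) - lw_ref + 1)))
  out <- tibble(
    log_kd_rel = (ref - fit$final_loglik + len_corr) / n_tot,
    lw = lw, lw_ref = lw_ref,
    final_loglik = fit$final_loglik, reference_loglik = ref,
    consensus = pwm_consensus(fit$model$pwm)
  )
  class(out) <- c("kd_estimate", class(out))
  out
}

#' Rank motifs by relative dissociation constant
#'
#' Ascending in `log_kd_rel`: the strongest binder (lowest KD) comes first.
#' Ties keep their input order.
#'
#' @param estimates a tibble with a `log_kd_rel` column (e.g. rows of
#'   [log_relative_kd()] outputs, or a [run_sweep()] results tibble).
#' @return the same tibble, reordered, with a `rank` column.
#' @export
rank_motifs <- function(estimates) {
  if (!is.data.frame(estimates) || !"log_kd_rel" %in% names(estimates))
    abort("expected a data frame with a log_kd_rel column")
  if (nrow(estimates) == 0L) abort("no estimates to rank")
  out <- estimates[order(estimates$log_kd_rel), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  out
}
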