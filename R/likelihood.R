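#' Energy models
#'
#' An energy model pairs a [pwm()] (sequence-specific Boltzmann weights)
#' with the log-weight `e0` of sequence-unspecific binding. `e0` lives in
#' `(-Inf, 0]`; `-Inf` means no unspecific binding at all (the convention
#' used for the dissociation-constant reference).
#'
#' @param pwm a `pwm`.
#' @param e0 unspecific-binding log-weight, in `(-Inf, 0]`.
#' @return an `energy_model`.
#' @export
energy_model <- function(pwm, e0 = -Inf) {
  if (!inherits(pwm, "pwm")) pwm <- bindnseq::pwm(pwm)
  if (is.na(e0) || e0 > 0) abort("e0 must lie in (-Inf, 0]")
  structure(list(pwm = pwm, e0 = e0), class = "energy_model")
}

#' @export
print.energy_model <- function(x, ...) {
  cat(sprintf("<energy_model> Lw=%d, consensus %s, e0=%.4g\n",
              nrow(x$pwm), pwm_consensus(x$pwm), x$e0))
  invisible(x)
}

#' Boltzmann weight of a binding site
#'
#' The weight of the protein sitting on one specific window is the product
#' of the PWM entries along that window, \eqn{e^{E(s)} = \prod_i
#' m_{i,s_i}}.
#'
#' @param pwm a `pwm` of length `Lw`.
#' @param sites character vector of `Lw`-mers.
#' @param log return natural-log weights.
#' @return numeric vector of site weights.
#' @examples
#' site_weight(uniform_pwm(5), "ACGTA") # 4^-5
#' @export
site_weight <- function(pwm, sites, log = FALSE) {
  lw <- nrow(pwm)
  sites <- toupper(sites)
  if (any(nchar(sites) != lw)) abort("sites must have length Lw")
  sm <- encode_seqs(sites)
  lm <- log(unclass(pwm))
  out <- numeric(length(sites))
  for (i in seq_len(lw)) out <- out + unname(lm[i, ])[sm[, i]]
  if (log) out else exp(out)
}

# window log-weights for an encoded equal-length group: n x (L - lw + 1)
window_logweights <- function(log_pwm, sm) {
  lw <- nrow(log_pwm)
  nwin <- ncol(sm) - lw + 1L
  out <- matrix(0, nrow = nrow(sm), ncol = nwin)
  for (j in seq_len(nwin)) {
    acc <- log_pwm[1L, ][sm[, j]]
    for (i in seq.int(2L, length.out = lw - 1L)) {
      acc <- acc + log_pwm[i, ][sm[, j + i - 1L]]
    }
    out[, j] <- acc
  }
  out
}

#' Total specific binding weight of a read
#'
#' Sums the site weights over every contiguous `Lw`-window of the read,
#' \eqn{e^{E(S)} = \sum_{s \in S} e^{E(s)}}, accumulated in log space.
#'
#' @param pwm a `pwm`.
#' @param reads character vector of reads, each at least `Lw` long.
#' @param log return the natural log of the summed weight.
#' @return numeric vector.
#' @examples
#' read_weight(uniform_pwm(5), strrep("A", 20)) # 16 * 4^-5
#' @export
read_weight <- function(pwm, reads, log = FALSE) {
  lw <- nrow(pwm)
  reads <- toupper(reads)
  if (any(nchar(reads) < lw)) abort("reads must be at least Lw long")
  lm <- log(unclass(pwm))
  out <- numeric(length(reads))
  for (L in unique(nchar(reads))) {
    sel <- nchar(reads) == L
    sm <- encode_seqs(reads[sel])
    out[sel] <- row_logsumexp(window_logweights(lm, sm))
  }
  if (log) out else exp(out)
}

#' Probability that a read is bound
#'
#' Under the thermodynamic model the occupancy of a read S at protein
#' concentration c is `c*W / (1 + c*W)` with
#' `W = e^{E(S)} + (L_S - Lw + 1) e^{e0}` combining specific binding in any
#' frame with unspecific binding anywhere on the read. When `c*W << 1`
#' (non-saturated selection) the linearized form `c*W` applies, in which the
#' concentration cancels from all selection probabilities.
#'
#' @param reads character vector of reads.
#' @param conc protein concentration `c >= 0` (arbitrary units).
#' @param model an `energy_model`.
#' @param linearized use the unsaturated linear form `c*W`.
#' @return numeric vector of probabilities (the linearized form may exceed 1
#'   outside its regime of validity).
#' @export
bound_probability <- function(reads, conc, model, linearized = FALSE) {
  stopifnot(inherits(model, "energy_model"), conc >= 0)
  lw <- nrow(model$pwm)
  nwin <- nchar(reads) - lw + 1L
  log_w <- logsumexp2(read_weight(model$pwm, reads, log = TRUE),
                      model$e0 + log(nwin))
  cw <- conc * exp(log_w)
  if (linearized) cw else cw / (1 + cw)
}

# ---------------------------------------------------------------------------
# likelihood context: precomputed encodings for one (library, lw) pair

lik_context <- function(library, lw, quiet = FALSE) {
  assert_library(library, annotated = TRUE)
  keep <- nchar(library$seq) >= lw
  if (!any(keep)) abort("no read is at least Lw long")
  if (!all(keep) && !quiet)
    inform(sprintf("dropped %d read(s) shorter than Lw=%d",
                   sum(!keep), lw))
  library <- library[keep, ]
  lens <- nchar(library$seq)
  groups <- lapply(unique(lens), function(L) {
    sel <- which(lens == L)
    list(rows = sel, sm = encode_seqs(library$seq[sel]),
         nwin = L - lw + 1L)
  })
  list(lw = lw, n = nrow(library),
       counts = library$count,
       log_prior = library$log_prior,
       log_nwin = log(lens - lw + 1),
       groups = groups,
       n_dropped = sum(!keep))
}

# per-distinct-read log specific weight e^{E(S)} under `log_pwm`
ctx_read_logweights <- function(ctx, log_pwm) {
  out <- numeric(ctx$n)
  for (g in ctx$groups) {
    out[g$rows] <- row_logsumexp(window_logweights(log_pwm, g$sm))
  }
  out
}

# log total weight log(e^{E(S)} + nwin * e^{e0}) from cached specific part
ctx_total_logweights <- function(ctx, log_ew, e0) {
  logsumexp2(log_ew, e0 + ctx$log_nwin)
}

# log-likelihood from cached specific weights
ctx_loglik <- function(ctx, log_ew, e0) {
  lt <- ctx_total_logweights(ctx, log_ew, e0)
  num <- ctx$log_prior + lt
  sum(ctx$counts * num) - sum(ctx$counts) * logsumexp(num)
}

#' Selection probability of each library read
#'
#' The probability that a sequenced, selected read is read S:
#' prior times bound-probability, normalized over the distinct reads of the
#' library (the concentration cancels). Returned for every record, in
#' library order; the values sum to 1.
#'
#' @param library an annotated `read_library`.
#' @param model an `energy_model`.
#' @return numeric vector of probabilities summing to 1.
#' @export
selection_probability <- function(library, model) {
  stopifnot(inherits(model, "energy_model"))
  ctx <- lik_context(library, nrow(model$pwm), quiet = TRUE)
  if (ctx$n != nrow(library))
    abort("every library read must be at least Lw long")
  log_ew <- ctx_read_logweights(ctx, log(unclass(model$pwm)))
  num <- ctx$log_prior + ctx_total_logweights(ctx, log_ew, model$e0)
  p <- exp(num - logsumexp(num))
  p / sum(p)
}

#' Log-likelihood of a selected read library
#'
#' The data log-likelihood of the selected pool under an energy model:
#' each distinct read contributes its copy number times the log of its
#' selection probability. All accumulation is in natural-log space; the
#' value is invariant to a global rescaling of the priors.
#'
#' @param library an annotated `read_library`; reads shorter than the PWM
#'   are dropped (with a message).
#' @param model an `energy_model`.
#' @return the log-likelihood (a non-positive real; `-Inf` if some read has
#'   zero total weight under a floor-0 PWM with `e0 = -Inf`).
#' @examples
#' lib <- as_read_library(c("ACGTACGT", "TGCATGCA"))
#' lib$log_prior <- log(rep(0.5, 2)); lib$prior <- rep(0.5, 2)
#' log_likelihood(lib, energy_model(uniform_pwm(5))) # 2*log(1/2)
#' @export
log_likelihood <- function(library, model) {
  stopifnot(inherits(model, "energy_model"))
  ctx <- lik_context(library, nrow(model$pwm))
  ctx_loglik(ctx, ctx_read_logweights(ctx, log(unclass(model$pwm))),
             model$e0)
}
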