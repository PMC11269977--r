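#' Initialize an energy model for an EM run
#'
#' Random mode draws every PWM position from a flat Dirichlet; consensus
#' mode plants a given motif (consensus base weight 0.7, others 0.1;
#' shorter motifs centered with uniform flanks). In both modes `e0` starts
#' at `log(1 / mean read length)` — unspecific binding to a typical read
#' initially weighs about as much as one generic site.
#'
#' @param lw motif length.
#' @param mode `"random"` or `"consensus"`.
#' @param consensus motif string (required for consensus mode).
#' @param seed RNG seed (random mode is bitwise reproducible given the seed).
#' @param mean_read_length sets the initial `e0 = log(1/mean_read_length)`.
#' @inheritParams pwm
#' @return an `energy_model`.
#' @export
init_model <- function(lw, mode = c("random", "consensus"), consensus = NULL,
                       seed = 1L, mean_read_length = 20, floor = 1e-9) {
  mode <- match.arg(mode)
  if (mode == "consensus") {
    if (is.null(consensus)) abort("consensus mode needs a motif string")
    p <- consensus_pwm(consensus, lw = lw, weight = 0.7, floor = floor)
  } else {
    set.seed(seed)
    g <- matrix(stats::rgamma(lw * 4L, shape = 1), nrow = lw)
    p <- pwm(g, floor = floor)
  }
  energy_model(p, e0 = log(1 / mean_read_length))
}

#' Maximize the likelihood over the unspecific-binding weight
#'
#' One-dimensional bounded maximization of the selection log-likelihood in
#' `e0`, holding the PWM fixed (golden-section/parabolic search on the
#' bracket, the same strategy as a Brent pass over the negative
#' log-likelihood). When no read has any specific weight, `e0` cancels from
#' the objective; that degenerate case is flagged and the bracket midpoint
#' returned.
#'
#' @param library an annotated `read_library`.
#' @param pwm a `pwm`.
#' @param bracket search interval `[lo, 0]`, `lo < 0`.
#' @param tol convergence tolerance of the 1-D search.
#' @return a list with `e0`, `loglik`, `at_edge` (optimum within `1e-4` of a
#'   bracket end) and `degenerate`.
#' @export
optimize_e0 <- function(library, pwm, bracket = c(-30, 0), tol = 1e-10) {
  ctx <- lik_context(library, nrow(pwm), quiet = TRUE)
  log_ew <- ctx_read_logweights(ctx, log(unclass(pwm)))
  optimize_e0_ctx(ctx, log_ew, bracket, tol)
}

optimize_e0_ctx <- function(ctx, log_ew, bracket = c(-30, 0), tol = 1e-10) {
  stopifnot(length(bracket) == 2L, bracket[1] < bracket[2], bracket[2] <= 0)
  if (all(is.infinite(log_ew) & log_ew < 0)) {
    warn("all specific read weights are zero; e0 is unidentifiable")
    mid <- mean(bracket)
    return(list(e0 = mid, loglik = ctx_loglik(ctx, log_ew, mid),
                at_edge = FALSE, degenerate = TRUE))
  }
  opt <- stats::optimize(function(e0) ctx_loglik(ctx, log_ew, e0),
                         interval = bracket, maximum = TRUE, tol = tol)
  at_edge <- min(opt$maximum - bracket[1], bracket[2] - opt$maximum) < 1e-4
  # the optimizer never lands exactly on an endpoint; if the optimum hugs an
  # edge, report the endpoint itself
  e0 <- opt$maximum
  if (at_edge) {
    edge <- bracket[which.min(abs(bracket - e0))]
    if (ctx_loglik(ctx, log_ew, edge) >= opt$objective) e0 <- edge
  }
  list(e0 = e0, loglik = ctx_loglik(ctx, log_ew, e0),
       at_edge = at_edge, degenerate = FALSE)
}

# analytic derivative of the log-likelihood in e0 (diagnostic residual)
e0_gradient <- function(library, pwm, e0) {
  ctx <- lik_context(library, nrow(pwm), quiet = TRUE)
  log_ew <- ctx_read_logweights(ctx, log(unclass(pwm)))
  lt <- ctx_total_logweights(ctx, log_ew, e0)
  frac <- exp(e0 + ctx$log_nwin - lt) # nwin*e^{e0} / W_S
  num <- ctx$log_prior + lt
  wden <- exp(num - logsumexp(num))
  sum(ctx$counts * frac) - sum(ctx$counts) * sum(wden * frac)
}

#' One EM reweighting update of the PWM
#'
#' Splits every read into its `Lw`-windows and adds, to the matrix entries
#' that window touches, the posterior weight of the protein binding exactly
#' there: `n_S * e^{E(s)} / (e^{E(S)} + (L_S - Lw + 1) e^{e0})`. The
#' accumulated matrix is then renormalized per position with the entry
#' floor.
#'
#' @param library an annotated `read_library`.
#' @param model an `energy_model`.
#' @inheritParams pwm
#' @return the updated `pwm`.
#' @export
update_pwm <- function(library, model, floor = 1e-9) {
  stopifnot(inherits(model, "energy_model"))
  ctx <- lik_context(library, nrow(model$pwm), quiet = TRUE)
  log_pwm <- log(unclass(model$pwm))
  update_pwm_ctx(ctx, log_pwm, model$e0, floor = floor)
}

update_pwm_ctx <- function(ctx, log_pwm, e0, floor = 1e-9) {
  lw <- nrow(log_pwm)
  acc <- matrix(0, nrow = lw, ncol = 4)
  for (g in ctx$groups) {
    wl <- window_logweights(log_pwm, g$sm)            # n x nwin
    log_ew <- row_logsumexp(wl)
    log_tot <- logsumexp2(log_ew, e0 + log(g$nwin))   # log W_S
    ok <- is.finite(log_tot)
    if (!any(ok)) next
    w <- ctx$counts[g$rows] * exp(wl - log_tot)       # posterior per window
    w[!ok, ] <- 0
    for (i in seq_len(lw)) {
      basecols <- g$sm[, i:(i + g$nwin - 1L), drop = FALSE]
      for (b in 1:4) acc[i, b] <- acc[i, b] + sum(w[basecols == b])
    }
  }
  if (any(rowSums(acc) <= 0))
    abort("PWM update received zero total weight at some position")
  normalize_pwm(acc, floor = floor)
}

#' Fit an energy model by expectation-maximization
#'
#' Alternates the `e0` maximization and the PWM reweighting update from an
#' initialized model until the squared PWM change drops below
#' `lw * 4 * tol` (mean squared change below `tol` per matrix entry) or
#' `max_iter` is reached. Records the log-likelihood trace and classifies
#' the run: *convergent* if the final log-likelihood exceeds the initial
#' one, *specific* if the fitted `e0` is negative (not pinned at the upper
#' bracket edge), so that the PWM rather than the unspecific term carries
#' the signal.
#'
#' @param library an annotated `read_library`; reads shorter than `lw` are
#'   dropped with a message.
#' @param lw motif length to fit.
#' @param init `"random"` or `"consensus"`.
#' @param consensus motif string for consensus initialization.
#' @param seed RNG seed for the initialization.
#' @param tol per-entry mean-squared PWM change declaring convergence.
#' @param max_iter iteration cap.
#' @param bracket `e0` search interval.
#' @inheritParams pwm
#' @return an `em_fit`: the fitted `energy_model` plus `lw`, `init_mode`,
#'   `seed`, `loglik_trace`, `initial_loglik`, `final_loglik`, `iterations`,
#'   `convergent`, `specific`, `e0_at_edge`, `e0_degenerate`, `n_reads`,
#'   `n_dropped`. Supports [generics::tidy()], [generics::glance()] and
#'   [ggplot2::autoplot()].
#' @export
fit_em <- function(library, lw, init = c("random", "consensus"),
                   consensus = NULL, seed = 1L, tol = 1e-6, max_iter = 500L,
                   bracket = c(-30, 0), floor = 1e-9) {
  init <- match.arg(init)
  ctx <- lik_context(library, lw)
  lens <- exp(ctx$log_nwin) + lw - 1 # read lengths, from window counts
  mean_len <- sum(lens * ctx$counts) / sum(ctx$counts)
  model <- init_model(lw, mode = init, consensus = consensus, seed = seed,
                      mean_read_length = mean_len, floor = floor)
  log_pwm <- log(unclass(model$pwm))
  e0 <- model$e0
  log_ew <- ctx_read_logweights(ctx, log_pwm)
  initial_loglik <- ctx_loglik(ctx, log_ew, e0)
  if (!is.finite(initial_loglik))
    abort("non-finite log-likelihood at initialization")

  trace <- numeric(0)
  threshold <- lw * 4 * tol
  converged <- FALSE
  at_edge <- FALSE
  degenerate <- FALSE
  it <- 0L
  p_old <- unclass(model$pwm)
  while (it < max_iter) {
    it <- it + 1L
    opt <- optimize_e0_ctx(ctx, log_ew, bracket = bracket)
    e0 <- opt$e0
    at_edge <- opt$at_edge
    degenerate <- opt$degenerate
    p_new <- unclass(update_pwm_ctx(ctx, log_pwm, e0, floor = floor))
    log_pwm <- log(p_new)
    log_ew <- ctx_read_logweights(ctx, log_pwm)
    ll <- ctx_loglik(ctx, log_ew, e0)
    if (!is.finite(ll)) abort(sprintf(
      "non-finite log-likelihood at iteration %d; run aborted", it))
    trace <- c(trace, ll)
    delta <- sum((p_new - p_old)^2)
    p_old <- p_new
    if (delta < threshold) { converged <- TRUE; break }
  }

  final_loglik <- trace[length(trace)]
  structure(
    list(
      model = energy_model(pwm(p_old, floor = floor), e0 = min(e0, 0)),
      lw = lw, init_mode = init, seed = seed,
      loglik_trace = trace,
      initial_loglik = initial_loglik, final_loglik = final_loglik,
      iterations = it, converged = converged,
      convergent = final_loglik > initial_loglik,
      # "specific": e0 strictly below 0, not pinned at the upper bracket edge
      specific = e0 < 0 && (bracket[2] - e0) > 1e-4,
      e0_at_edge = at_edge, e0_degenerate = degenerate,
      n_reads = sum(ctx$counts), n_dropped = ctx$n_dropped
    ),
    class = "em_fit"
  )
}

#' @export
print.em_fit <- function(x, ...) {
  cat(sprintf(
    paste0("<em_fit> Lw=%d (%s init, seed %d): %d iteration(s), logL %.4f ",
           "-> %.4f\n  e0=%.4g | convergent: %s, specific: %s\n"),
    x$lw, x$init_mode, x$seed, x$iterations, x$initial_loglik,
    x$final_loglik, x$model$e0, x$convergent, x$specific))
  cat(sprintf("  consensus: %s\n", pwm_consensus(x$model$pwm)))
  invisible(x)
}

#' Summarize a collection of EM runs
#'
#' Pools runs (typically across motif lengths and initializations) and
#' reports how many were convergent, and convergent **and** specific —
#' runs where unspecific binding did not dominate, so the PWM is
#' interpretable.
#'
#' @param results a list of `em_fit` objects, or the tibble returned by
#'   [run_sweep()].
#' @return a one-row tibble: `n_runs`, `n_convergent`,
#'   `n_convergent_specific`, `frac_convergent`, `frac_convergent_specific`.
#' @export
classify_runs <- function(results) {
  if (is.data.frame(results)) {
    conv <- results$convergent
    spec <- results$specific
  } else {
    if (length(results) == 0L) abort("no runs to classify")
    conv <- vapply(results, `[[`, logical(1), "convergent")
    spec <- vapply(results, `[[`, logical(1), "specific")
  }
  n <- length(conv)
  tibble(
    n_runs = n,
    n_convergent = sum(conv),
    n_convergent_specific = sum(conv & spec),
    frac_convergent = sum(conv) / n,
    frac_convergent_specific = sum(conv & spec) / n
  )
}
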