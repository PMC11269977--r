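#' Sample a synthetic input (background) pool
#'
#' Draws i.i.d. reads from a composition-bias model: either per-base
#' probabilities (e.g. the A-rich pools seen in real input libraries) or a
#' full `markov_background`, in which case reads follow the chain. Results
#' are deterministic given the seed.
#'
#' @param n number of reads.
#' @param read_length read length in nt (default 20, the typical Bind'n Seq
#'   oligomer length).
#' @param bias numeric length-4 probability vector (A,C,G,T) or a
#'   `markov_background`.
#' @param seed RNG seed.
#' @return character vector of `n` reads.
#' @export
simulate_background <- function(n, read_length = 20,
                                bias = c(A = 0.25, C = 0.25,
                                         G = 0.25, T = 0.25),
                                seed = 1L) {
  stopifnot(n >= 1, read_length >= 1)
  set.seed(seed)
  if (inherits(bias, "markov_background")) {
    d <- bias$degree
    if (read_length < max(d, 1L))
      abort("read_length shorter than the Markov degree")
    sm <- matrix(0L, nrow = n, ncol = read_length)
    if (d > 0L) {
      ctx <- sample.int(length(bias$initial), n, replace = TRUE,
                        prob = bias$initial)
      # unpack context code into its d bases (first base most significant)
      code <- ctx - 1L
      for (k in d:1) {
        sm[, k] <- code %% 4L + 1L
        code <- code %/% 4L
      }
    } else {
      ctx <- rep(1L, n)
    }
    u <- matrix(stats::runif(n * (read_length - d)), nrow = n)
    cum <- t(apply(bias$trans, 1, cumsum))
    for (t in seq.int(d + 1L, length.out = read_length - d)) {
      b <- 1L + (u[, t - d] > cum[ctx, 1L]) + (u[, t - d] > cum[ctx, 2L]) +
        (u[, t - d] > cum[ctx, 3L])
      sm[, t] <- b
      if (d > 0L) {
        ctx <- if (d == 1L) b else ((ctx - 1L) %% 4L^(d - 1L)) * 4L + b
      }
    }
  } else {
    if (length(bias) != 4L || any(bias < 0) || sum(bias) <= 0)
      abort("bias must be 4 non-negative probabilities or a markov_background")
    bias <- bias / sum(bias)
    sm <- matrix(sample.int(4L, n * read_length, replace = TRUE,
                            prob = bias),
                 nrow = n)
  }
  decode_seqmat(sm)
}

decode_seqmat <- function(sm) {
  chars <- matrix(BASES[sm], nrow = nrow(sm))
  apply(chars, 1, paste0, collapse = "")
}

# exact generator probability of each read under the bias used to sample it
bias_log_prior <- function(seqs, bias) {
  if (inherits(bias, "markov_background")) {
    sequence_prior(bias, seqs, log = TRUE)
  } else {
    bias <- bias / sum(bias)
    sm <- encode_seqs(seqs)
    lp <- log(bias)
    rowSums(matrix(lp[sm], nrow = nrow(sm)))
  }
}

#' Simulate affinity selection of an oligomer pool
#'
#' Generates a synthetic Bind'n Seq experiment: an input pool drawn from a
#' composition bias, and a selected (foreground) pool drawn with replacement
#' from the distinct input sequences with probability proportional to
#' `prior x bound-probability` under a planted energy model — the same
#' selection law the inference assumes. Priors are the exact generator
#' probabilities, so the sampled frequencies match the model's selection
#' probabilities in the large-sample limit. In `"linearized"` mode the
#' concentration cancels; the run aborts if `conc * max(W)` exceeds 0.01,
#' since the linear form only describes unsaturated selection. With
#' `conc = 0` in full mode there is no selection signal: the foreground is
#' drawn from the priors alone and flagged.
#'
#' @param pwm the planted `pwm`.
#' @param e0 planted unspecific-binding log-weight (`-Inf` for none).
#' @param conc protein concentration (arbitrary units).
#' @param n_background,n_foreground pool sizes.
#' @param background optional character vector to use as the input pool
#'   (otherwise sampled here from `bias`).
#' @inheritParams simulate_background
#' @param mode `"linearized"` (unsaturated, concentration-free) or
#'   `"full"` (saturating occupancy).
#' @return a list of class `bns_simulation`: `background` and `foreground`
#'   read vectors, `candidates` (annotated `read_library` of distinct input
#'   sequences with their selection probabilities in `sel_prob`), `truth`
#'   (planted parameters incl. seed) and `no_selection` flag.
#' @export
simulate_selection <- function(pwm, e0 = -Inf, conc = 1e-3,
                               n_background = 1e4, n_foreground = 1e4,
                               read_length = 20,
                               bias = c(A = 0.25, C = 0.25,
                                        G = 0.25, T = 0.25),
                               background = NULL,
                               mode = c("linearized", "full"),
                               seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(inherits(pwm, "pwm") || is.matrix(pwm))
  if (!inherits(pwm, "pwm")) pwm <- bindnseq::pwm(pwm)
  if (e0 > 0) abort("planted e0 must lie in (-Inf, 0]")
  if (conc < 0) abort("conc must be >= 0")
  if (is.null(background)) {
    background <- simulate_background(n_background, read_length, bias,
                                      seed = seed)
  }
  cand <- unique(background)
  if (any(nchar(cand) < nrow(pwm)))
    abort("background reads must be at least as long as the planted PWM")
  log_prior <- bias_log_prior(cand, bias)
  model <- energy_model(pwm, e0 = e0)

  lw <- nrow(pwm)
  nwin <- nchar(cand) - lw + 1L
  log_w <- logsumexp2(read_weight(pwm, cand, log = TRUE),
                      e0 + log(nwin))
  no_selection <- FALSE
  if (mode == "linearized") {
    if (conc * exp(max(log_w)) >= 0.01)
      abort("linearized mode requires conc * max(W) < 0.01 (unsaturated)")
    log_sel <- log_prior + log_w # conc cancels after normalization
  } else {
    cw <- conc * exp(log_w)
    if (all(cw == 0)) {
      no_selection <- TRUE
      warn("conc = 0: no selection; foreground drawn from priors alone")
      log_sel <- log_prior
    } else {
      log_sel <- log_prior + log(cw) - log1p(cw)
    }
  }
  sel_prob <- exp(log_sel - logsumexp(log_sel))
  sel_prob <- sel_prob / sum(sel_prob)
  set.seed(derive_seed(seed, lw, 2L))
  fg_idx <- sample.int(length(cand), n_foreground, replace = TRUE,
                       prob = sel_prob)
  foreground <- cand[fg_idx]

  candidates <- tibble(
    seq = cand, count = 1L,
    prior = exp(log_prior), log_prior = log_prior,
    sel_prob = sel_prob
  )
  class(candidates) <- c("read_library", class(tibble()))

  structure(
    list(
      background = background,
      foreground = foreground,
      candidates = candidates,
      truth = list(pwm = pwm, e0 = e0, conc = conc, mode = mode,
                   seed = seed, read_length = read_length,
                   bias = bias),
      no_selection = no_selection
    ),
    class = "bns_simulation"
  )
}

#' @export
print.bns_simulation <- function(x, ...) {
  cat(sprintf(
    "<bns_simulation> planted %s (Lw=%d, e0=%.3g, %s mode)\n  %d background / %d foreground reads of length %d\n",
    pwm_consensus(x$truth$pwm), nrow(x$truth$pwm), x$truth$e0,
    x$truth$mode, length(x$background), length(x$foreground),
    x$truth$read_length))
  invisible(x)
}

#' Write a simulation to FASTA plus a ground-truth JSON
#'
#' Emits `<prefix>_background.fasta.gz`, `<prefix>_foreground.fasta.gz` and
#' `<prefix>_truth.json` (planted PWM, e0, concentration, mode, seed).
#'
#' @param sim a `bns_simulation`.
#' @param prefix output path prefix.
#' @return character vector of the three paths, invisibly.
#' @export
write_simulation <- function(sim, prefix) {
  stopifnot(inherits(sim, "bns_simulation"))
  paths <- c(
    background = paste0(prefix, "_background.fasta.gz"),
    foreground = paste0(prefix, "_foreground.fasta.gz"),
    truth = paste0(prefix, "_truth.json")
  )
  write_reads_fasta(sim$background, paths[["background"]])
  write_reads_fasta(sim$foreground, paths[["foreground"]])
  tr <- sim$truth
  jsonlite::write_json(
    list(pwm = unclass(tr$pwm), e0 = tr$e0, conc = tr$conc,
         mode = tr$mode, seed = tr$seed, read_length = tr$read_length),
    paths[["truth"]], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
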