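#' Train an order-d Markov background model
#'
#' The unselected input pool of a Bind'n Seq experiment carries composition
#' biases (A-richness is common). An order-`degree` Markov chain trained on
#' that pool predicts the expected frequency of any read under no selection;
#' these frequencies serve as the priors \eqn{f_S} of the selection
#' likelihood. Counts are regularized with an additive pseudocount per
#' context-base cell, so every transition probability is strictly positive.
#'
#' @param reads a `read_library`, or a character vector of A/C/G/T reads.
#'   Library copy numbers weight the counts.
#' @param degree non-negative Markov order `d`; every read must be longer
#'   than `d`. The default 4 resolves pentamer-scale composition bias, the
#'   length scale of typical RBP binding sites.
#' @param pseudocount positive additive regularizer per context-base cell.
#' @param max_contexts guard against accidental huge `degree`: training
#'   errors out if `4^degree` exceeds this.
#' @return a `markov_background` object with fields `degree`, `pseudocount`,
#'   `initial` (probability of each leading d-mer) and `trans`
#'   (`4^degree` x 4 matrix of transition probabilities).
#' @examples
#' m <- train_markov(c("ACGT", "ACGA"), degree = 1, pseudocount = 0)
#' m$trans["A", ] # C follows A with probability 1
#' @export
train_markov <- function(reads, degree = 4, pseudocount = 1,
                         max_contexts = 4^10) {
  if (is.data.frame(reads)) {
    assert_library(reads)
    counts <- reads$count
    seqs <- reads$seq
  } else {
    seqs <- toupper(as.character(reads))
    counts <- rep(1L, length(seqs))
  }
  if (length(seqs) == 0L) abort("cannot train on an empty read collection")
  degree <- as.integer(degree)
  if (degree < 0L) abort("degree must be >= 0")
  n_ctx <- 4^degree
  if (n_ctx > max_contexts)
    abort(sprintf(
      "degree %d implies %g contexts (> max_contexts); use a lower degree",
      degree, n_ctx))
  if (pseudocount < 0) abort("pseudocount must be >= 0")
  if (any(nchar(seqs) <= degree))
    abort("every read must be longer than the Markov degree")

  contexts <- if (degree == 0L) "" else
    apply(expand.grid(rep(list(BASES), degree))[, degree:1, drop = FALSE],
          1, paste0, collapse = "")

  init_counts <- numeric(n_ctx)
  trans_counts <- matrix(0, nrow = n_ctx, ncol = 4,
                         dimnames = list(contexts, BASES))

  # group by read length so encoding is a matrix per group
  for (L in unique(nchar(seqs))) {
    sel <- nchar(seqs) == L
    sm <- encode_seqs(seqs[sel])
    w <- counts[sel]
    if (degree > 0L) {
      ctx0 <- ctx_codes(sm, 1L, degree)
      init_counts <- init_counts + tab_weighted(ctx0, w, n_ctx)
    } else {
      init_counts <- init_counts + sum(w)
    }
    for (t in seq.int(degree + 1L, L)) {
      ctx <- if (degree == 0L) rep(1L, nrow(sm)) else
        ctx_codes(sm, t - degree, degree)
      cell <- (ctx - 1L) * 4L + sm[, t]
      tc <- tab_weighted(cell, w, n_ctx * 4L)
      trans_counts <- trans_counts + matrix(tc, nrow = n_ctx, byrow = TRUE)
    }
  }

  initial <- (init_counts + pseudocount) /
    (sum(init_counts) + n_ctx * pseudocount)
  names(initial) <- contexts
  trans <- (trans_counts + pseudocount) /
    (rowSums(trans_counts) + 4 * pseudocount)
  # pseudocount 0 with an unseen context leaves 0/0; keep such rows uniform
  bad <- rowSums(trans_counts) + 4 * pseudocount == 0
  trans[bad, ] <- 0.25

  structure(
    list(degree = degree, pseudocount = pseudocount,
         initial = initial, trans = trans),
    class = "markov_background"
  )
}

# integer context codes (1-based) for the d-mer starting at column `from`
ctx_codes <- function(sm, from, degree) {
  code <- integer(nrow(sm))
  for (k in seq_len(degree)) {
    code <- code * 4L + (sm[, from + k - 1L] - 1L)
  }
  code + 1L
}

# weighted tabulate: rowsum drops empty bins, so scatter back explicitly
tab_weighted <- function(idx, w, nbins) {
  out <- numeric(nbins)
  t <- rowsum(as.numeric(w), idx)
  out[as.integer(rownames(t))] <- t[, 1L]
  out
}

#' @export
print.markov_background <- function(x, ...) {
  cat(sprintf("<markov_background> order d=%d, pseudocount=%g, %d contexts\n",
              x$degree, x$pseudocount, nrow(x$trans)))
  invisible(x)
}

#' Probability of a sequence under a Markov background model
#'
#' Returns the chain probability: the initial distribution evaluated on the
#' leading d-mer times the product of transition probabilities along the
#' sequence. Summed over all `4^L` sequences of a fixed length `L` this
#' equals 1, so the value is a proper length-conditional probability.
#'
#' @param model a `markov_background`.
#' @param sequences character vector of A/C/G/T sequences, each at least
#'   `degree` long (at least 1 for degree 0).
#' @param log return natural-log probabilities.
#' @return numeric vector of (log-)probabilities.
#' @export
sequence_prior <- function(model, sequences, log = FALSE) {
  stopifnot(inherits(model, "markov_background"))
  sequences <- toupper(sequences)
  if (!all(is_acgt(sequences))) abort("sequences must be A/C/G/T")
  d <- model$degree
  if (any(nchar(sequences) < max(d, 1L)))
    abort("sequence shorter than the Markov degree")
  log_init <- log(model$initial)
  log_trans <- log(model$trans)
  out <- numeric(length(sequences))
  for (L in unique(nchar(sequences))) {
    sel <- nchar(sequences) == L
    sm <- encode_seqs(sequences[sel])
    lp <- if (d > 0L) log_init[ctx_codes(sm, 1L, d)] else numeric(nrow(sm))
    if (L > d) {
      for (t in seq.int(d + 1L, L)) {
        ctx <- if (d == 0L) rep(1L, nrow(sm)) else ctx_codes(sm, t - d, d)
        lp <- lp + log_trans[cbind(ctx, sm[, t])]
      }
    }
    out[sel] <- lp
  }
  if (log) out else exp(out)
}

#' Annotate a read library with frequency priors
#'
#' Sets each record's `prior`/`log_prior` to its probability under the
#' background model. Priors are stored on the raw Markov-chain scale
#' (normalized over all sequences of each length); the selection likelihood
#' is invariant to any global rescaling, so an optional `rescale` constant is
#' provided purely for presentation (e.g. normalizing over an observed pool).
#'
#' @param library a `read_library`.
#' @param model a trained `markov_background`.
#' @param rescale positive multiplicative constant applied to all priors.
#' @return the library with `prior` and `log_prior` filled in. Reads shorter
#'   than the model degree are dropped with a warning.
#' @export
annotate_priors <- function(library, model, rescale = 1) {
  assert_library(library)
  stopifnot(inherits(model, "markov_background"), rescale > 0)
  ok <- nchar(library$seq) >= max(model$degree, 1L)
  if (!any(ok)) abort("no read is long enough for this model degree")
  if (!all(ok)) {
    warn(sprintf("dropped %d read(s) shorter than the Markov degree",
                 sum(!ok)))
    library <- library[ok, ]
  }
  lp <- sequence_prior(model, library$seq, log = TRUE) + log(rescale)
  library$log_prior <- lp
  library$prior <- exp(lp)
  library
}

#' Serialize / deserialize a Markov background model as JSON
#'
#' Contexts are stored as literal d-mer strings, so files are readable and
#' stable across sessions.
#'
#' @param model a `markov_background`.
#' @param path file path.
#' @return `write_markov_json` returns `path` invisibly; `read_markov_json`
#'   returns the model.
#' @export
write_markov_json <- function(model, path) {
  stopifnot(inherits(model, "markov_background"))
  obj <- list(
    degree = model$degree,
    pseudocount = model$pseudocount,
    initial_dist = as.list(stats::setNames(model$initial,
                                           names(model$initial))),
    transitions = stats::setNames(
      lapply(seq_len(nrow(model$trans)),
             function(i) as.list(stats::setNames(model$trans[i, ], BASES))),
      rownames(model$trans))
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_markov_json
#' @export
read_markov_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  trans <- do.call(rbind, lapply(obj$transitions, function(r)
    unlist(r)[BASES]))
  rownames(trans) <- names(obj$transitions)
  colnames(trans) <- BASES
  initial <- unlist(obj$initial_dist)
  if (is.null(names(initial)) || obj$degree == 0L) names(initial) <- ""
  structure(
    list(degree = as.integer(obj$degree), pseudocount = obj$pseudocount,
         initial = initial, trans = trans),
    class = "markov_background"
  )
}
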