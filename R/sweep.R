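#' Run a motif-length sweep of EM fits
#'
#' The full inference pipeline on one foreground/background pair: train the
#' background Markov model, annotate the foreground with priors, then for
#' every motif length run `n_random` randomly initialized EM fits plus
#' `n_consensus` consensus-seeded ones (if a consensus is given). Per-run
#' seeds are a pure function of `(seed, lw, run index)`, so a sweep is
#' bitwise reproducible and runs are independent of execution order.
#' Relative KDs are computed for every convergent run.
#'
#' @param foreground,bg a `read_library` (or character vector / FASTA-FASTQ
#'   path) of selected and input reads respectively.
#' @param lw integer vector of motif lengths to fit (default `5:15`).
#' @param n_random random initializations per length (default 16).
#' @param n_consensus consensus-seeded initializations per length (default 4
#'   when `consensus` is given, else 0).
#' @param consensus optional consensus motif string.
#' @param degree,pseudocount background Markov model settings.
#' @param tol,max_iter,floor EM settings (see [fit_em()]).
#' @param lw_ref reference motif length for relative KDs.
#' @param seed base seed.
#' @param out_dir optional directory: writes `results.tsv`, per-run PWM
#'   TSVs, and `best_pwm.meme`/`best_pwm.tsv`.
#' @return a `bns_sweep` tibble, one row per run — `lw`, `init_mode`,
#'   `seed`, `iterations`, `initial_loglik`, `final_loglik`, `e0`,
#'   `convergent`, `specific`, `log_kd_rel`, `consensus`, `fit`
#'   (list-column of `em_fit`s). Failed runs are dropped with a warning
#'   naming how many. `summary(x)`/[classify_runs()] give the pooled
#'   convergent/specific fractions, [best_fit()] the top-ranked run.
#' @export
run_sweep <- function(foreground, bg, lw = 5:15,
                      n_random = 16, n_consensus = if (is.null(consensus)) 0 else 4,
                      consensus = NULL,
                      degree = 4, pseudocount = 1,
                      tol = 1e-6, max_iter = 500L, floor = 1e-9,
                      lw_ref = 5, seed = 1L, out_dir = NULL) {
  fg_lib <- as_library_input(foreground)
  bg_lib <- as_library_input(bg)
  if (max(lw) > max(nchar(fg_lib$seq)))
    abort("largest lw exceeds the longest foreground read")
  model_bg <- train_markov(bg_lib, degree = degree,
                           pseudocount = pseudocount)
  fg_lib <- annotate_priors(fg_lib, model_bg)

  plan <- tidyr::expand_grid(
    lw = as.integer(lw),
    idx = seq_len(n_random + n_consensus)
  )
  plan$init_mode <- ifelse(plan$idx <= n_random, "random", "consensus")
  plan$run_seed <- derive_seed(seed, plan$lw, plan$idx)

  fits <- purrr::pmap(plan, function(lw, idx, init_mode, run_seed) {
    # a consensus longer than the motif being fitted is center-truncated
    cns <- if (!is.null(consensus) && nchar(consensus) > lw) {
      off <- (nchar(consensus) - lw) %/% 2
      substr(consensus, off + 1, off + lw)
    } else consensus
    tryCatch(
      fit_em(fg_lib, lw = lw, init = init_mode, consensus = cns,
             seed = run_seed, tol = tol, max_iter = max_iter,
             floor = floor),
      error = function(e) e
    )
  })
  failed <- vapply(fits, inherits, logical(1), "error")
  if (any(failed))
    warn(sprintf("%d of %d run(s) failed and were excluded: %s",
                 sum(failed), length(fits),
                 conditionMessage(fits[[which(failed)[1]]])))
  plan <- plan[!failed, ]
  fits <- fits[!failed]
  if (length(fits) == 0L) abort("all runs failed")

  rows <- purrr::map2(fits, seq_along(fits), function(f, i) {
    kd <- if (f$convergent)
      log_relative_kd(f, fg_lib, lw_ref = lw_ref)$log_kd_rel
    else NA_real_
    tibble(
      lw = f$lw, init_mode = f$init_mode, seed = f$seed,
      iterations = f$iterations,
      initial_loglik = f$initial_loglik, final_loglik = f$final_loglik,
      e0 = f$model$e0, convergent = f$convergent, specific = f$specific,
      log_kd_rel = kd, consensus = pwm_consensus(f$model$pwm)
    )
  })
  out <- dplyr::bind_rows(rows)
  out$fit <- fits
  class(out) <- c("bns_sweep", class(out))
  attr(out, "lw_ref") <- lw_ref
  attr(out, "background_model") <- model_bg

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_results_tsv(out, file.path(out_dir, "results.tsv"))
    for (i in seq_len(nrow(out))) {
      write_pwm_tsv(out$fit[[i]]$model$pwm,
                    file.path(out_dir, sprintf("pwm_lw%02d_%s_seed%d.tsv",
                                               out$lw[i], out$init_mode[i],
                                               out$seed[i])))
    }
    best <- best_fit(out)
    if (!is.null(best)) {
      write_pwm_tsv(best$model$pwm, file.path(out_dir, "best_pwm.tsv"))
      write_pwm_meme(best$model$pwm, file.path(out_dir, "best_pwm.meme"))
    }
  }
  out
}

as_library_input <- function(x) {
  if (is.data.frame(x)) { assert_library(x); return(x) }
  if (is.character(x) && length(x) == 1L && file.exists(x))
    return(read_library(x))
  as_read_library(x)
}

#' Best run of a sweep
#'
#' Among convergent and specific runs, highest final log-likelihood wins;
#' near-ties (within 1e-6) go to the lower (more specific) `e0`, then to
#' the smaller seed.
#'
#' @param sweep a `bns_sweep`.
#' @return the winning `em_fit`, or `NULL` if no run is convergent and
#'   specific.
#' @export
best_fit <- function(sweep) {
  stopifnot(inherits(sweep, "bns_sweep"))
  ok <- which(sweep$convergent & sweep$specific)
  if (length(ok) == 0L) return(NULL)
  cand <- sweep[ok, ]
  top_ll <- max(cand$final_loglik)
  tied <- which(cand$final_loglik > top_ll - 1e-6)
  tied <- tied[order(cand$e0[tied], cand$seed[tied])]
  cand$fit[[tied[1]]]
}

#' @export
summary.bns_sweep <- function(object, ...) {
  classify_runs(object)
}

#' Write / read a sweep results table as TSV
#'
#' One row per run; the `fit` list-column is dropped on write.
#'
#' @param sweep a `bns_sweep` (writer) or path (reader).
#' @param path output path.
#' @return path (writer, invisibly); tibble (reader).
#' @export
write_results_tsv <- function(sweep, path) {
  cols <- setdiff(names(sweep), "fit")
  readr::write_tsv(as_tibble(sweep)[, cols], path)
  invisible(path)
}

#' @rdname write_results_tsv
#' @export
read_results_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}
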