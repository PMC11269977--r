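#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy an EM fit into a long PWM tibble
#'
#' @param x an `em_fit`.
#' @param ... unused.
#' @return tibble with `position`, `base`, `probability`.
#' @method tidy em_fit
#' @export
tidy.em_fit <- function(x, ...) {
  m <- unclass(x$model$pwm)
  tibble(
    position = rep(seq_len(nrow(m)), times = 4L),
    base = rep(BASES, each = nrow(m)),
    probability = as.vector(m)
  )
}

#' One-row summary of an EM fit
#'
#' @param x an `em_fit`.
#' @param ... unused.
#' @return one-row tibble: `lw`, `init_mode`, `seed`, `iterations`,
#'   `initial_loglik`, `final_loglik`, `e0`, `convergent`, `specific`,
#'   `consensus`.
#' @method glance em_fit
#' @export
glance.em_fit <- function(x, ...) {
  tibble(
    lw = x$lw, init_mode = x$init_mode, seed = x$seed,
    iterations = x$iterations,
    initial_loglik = x$initial_loglik, final_loglik = x$final_loglik,
    e0 = x$model$e0, convergent = x$convergent, specific = x$specific,
    consensus = pwm_consensus(x$model$pwm)
  )
}

#' Plot an EM fit: log-likelihood trace and fitted PWM
#'
#' @param object an `em_fit`.
#' @param what `"trace"` or `"pwm"`.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot em_fit
#' @export
autoplot.em_fit <- function(object, what = c("trace", "pwm"), ...) {
  what <- match.arg(what)
  if (what == "trace") {
    df <- tibble(iteration = seq_along(object$loglik_trace),
                 loglik = object$loglik_trace)
    ggplot2::ggplot(df, ggplot2::aes(.data$iteration, .data$loglik)) +
      ggplot2::geom_line() + ggplot2::geom_point(size = 0.8) +
      ggplot2::labs(x = "EM iteration", y = "log-likelihood",
                    title = sprintf("Lw = %d (%s init)", object$lw,
                                    object$init_mode)) +
      ggplot2::theme_minimal()
  } else {
    plot_pwm(object$model$pwm)
  }
}

#' Heatmap of a PWM
#'
#' @param x a `pwm`.
#' @return a ggplot tile map of per-position base probabilities.
#' @export
plot_pwm <- function(x) {
  m <- unclass(x)
  df <- tibble(
    position = rep(seq_len(nrow(m)), times = 4L),
    base = factor(rep(BASES, each = nrow(m)), levels = rev(BASES)),
    probability = as.vector(m)
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$position, .data$base,
                                   fill = .data$probability)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(
      label = sprintf("%.2f", .data$probability)), size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue",
                                 limits = c(0, 1)) +
    ggplot2::scale_x_continuous(breaks = seq_len(nrow(m))) +
    ggplot2::labs(x = "motif position", y = NULL) +
    ggplot2::theme_minimal()
}

#' Ranked enrichment curve (leaderboard plot)
#'
#' @param object an `enrichment_table`.
#' @param label_top annotate this many leading k-mers.
#' @param ... unused.
#' @return a ggplot of log-enrichment against rank.
#' @method autoplot enrichment_table
#' @export
autoplot.enrichment_table <- function(object, label_top = 5, ...) {
  df <- dplyr::arrange(as_tibble(object), .data$rank)
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$rank,
                                        .data$log_enrichment)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "k-mer rank", y = "log enrichment (natural log)") +
    ggplot2::theme_minimal()
  if (label_top > 0) {
    p <- p + ggplot2::geom_text(
      data = df[seq_len(min(label_top, nrow(df))), ],
      ggplot2::aes(label = .data$kmer),
      hjust = -0.1, vjust = -0.4, size = 3)
  }
  p
}

#' Convergent/specific run-fraction plot
#'
#' @param object a `bns_sweep`.
#' @param ... unused.
#' @return a ggplot bar chart of pooled run fractions.
#' @method autoplot bns_sweep
#' @export
autoplot.bns_sweep <- function(object, ...) {
  s <- classify_runs(object)
  df <- tibble(
    outcome = factor(c("convergent", "convergent & specific"),
                     levels = c("convergent", "convergent & specific")),
    fraction = c(s$frac_convergent, s$frac_convergent_specific)
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$outcome, .data$fraction)) +
    ggplot2::geom_col(width = 0.5, fill = "grey30") +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = NULL, y = "fraction of runs") +
    ggplot2::theme_minimal()
}
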