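#' Diagnostic plot for a BUM fit
#'
#' Left panel: histogram of the p-values with the fitted mixture density, its
#' uniform (null) component and its Beta(a, 1) (signal) component. Right
#' panel: quantile-quantile plot of the empirical p-values against the fitted
#' mixture distribution.
#'
#' @param object A `bum_fit`.
#' @param bins Histogram bin count.
#' @param ... Unused.
#' @return A patchwork of two ggplots.
#' @exportS3Method ggplot2::autoplot
autoplot.bum_fit <- function(object, bins = 40, ...) {
  a <- object$a
  lambda <- object$lambda
  df <- tibble(pvalue = object$pvalues)
  xs <- seq(1e-4, 1, length.out = 400)
  dens <- tibble(
    x = rep(xs, 3),
    density = c(
      bum_pdf(xs, a, lambda),
      rep(lambda, length(xs)),
      (1 - lambda) * a * xs^(a - 1)
    ),
    component = rep(c("mixture", "uniform (null)", "beta signal"), each = length(xs))
  )
  p_hist <- ggplot2::ggplot(df, ggplot2::aes(x = .data$pvalue)) +
    ggplot2::geom_histogram(
      ggplot2::aes(y = ggplot2::after_stat(density)),
      bins = bins, fill = "grey85", colour = "grey60"
    ) +
    ggplot2::geom_line(
      data = dens,
      ggplot2::aes(x = .data$x, y = .data$density, colour = .data$component)
    ) +
    ggplot2::coord_cartesian(ylim = c(0, stats::quantile(bum_pdf(df$pvalue, a, lambda), 0.98))) +
    ggplot2::labs(x = "p-value", y = "density", colour = NULL) +
    ggplot2::theme_minimal()

  # theoretical quantiles by inverting the mixture CDF numerically
  n <- length(object$pvalues)
  probs <- (seq_len(n) - 0.5) / n
  cdf <- function(x) lambda * x + (1 - lambda) * x^a
  theo <- vapply(probs, function(p) {
    stats::uniroot(function(x) cdf(x) - p, c(1e-300, 1), tol = 1e-12)$root
  }, numeric(1))
  qq <- tibble(theoretical = theo, empirical = sort(object$pvalues))
  p_qq <- ggplot2::ggplot(qq, ggplot2::aes(x = .data$theoretical, y = .data$empirical)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey60") +
    ggplot2::geom_point(size = 0.6, alpha = 0.6) +
    ggplot2::labs(x = "fitted mixture quantiles", y = "empirical p-values") +
    ggplot2::theme_minimal()

  patchwork::wrap_plots(p_hist, p_qq, ncol = 2)
}

#' Plot a Pareto front
#'
#' Activity score against pathway coverage for every front member, with the
#' extreme and knee solutions labelled.
#'
#' @param object A `pareto_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.pareto_result <- function(object, ...) {
  front <- object$front
  ggplot2::ggplot(front, ggplot2::aes(x = .data$s_a, y = .data$r_a)) +
    ggplot2::geom_step(direction = "vh", colour = "grey70") +
    ggplot2::geom_point(ggplot2::aes(colour = !is.na(.data$label)), size = 2) +
    ggplot2::geom_text(
      data = front[!is.na(front$label), ],
      ggplot2::aes(label = .data$label),
      vjust = -0.8, size = 3
    ) +
    ggplot2::scale_colour_manual(
      values = c(`TRUE` = "firebrick", `FALSE` = "grey30"), guide = "none"
    ) +
    ggplot2::labs(
      x = expression("module activity " * S[A]),
      y = expression("pathways covered " * R[A])
    ) +
    ggplot2::theme_minimal()
}

#' Plot search progress
#'
#' Best feasible activity score and pathway coverage per generation.
#'
#' @param result A `pareto_result`.
#' @return A ggplot.
#' @export
plot_history <- function(result) {
  h <- tidyr::pivot_longer(result$history,
    cols = c("best_s_a", "best_r_a"),
    names_to = "objective", values_to = "best"
  )
  ggplot2::ggplot(h, ggplot2::aes(x = .data$generation, y = .data$best)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~objective, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "generation", y = "best feasible objective") +
    ggplot2::theme_minimal()
}
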