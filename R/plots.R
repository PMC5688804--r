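#' Plot a fitted marker mixture over the data
#'
#' Histogram of the marker expression values with the two fitted Gaussian
#' components and the resulting mixture density overlaid.
#'
#' @param object A `marker_fit` from [fit_two_component()].
#' @param values The expression values the fit was trained on (optional;
#'   densities alone are drawn when omitted).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.marker_fit <- function(object, values = NULL, ...) {
  lim <- range(object$mu + c(-4, 4) * sqrt(max(object$sigma2)))
  if (!is.null(values)) lim <- range(lim, values)
  grid <- seq(lim[1], lim[2], length.out = 400)
  dens <- bind_rows(
    tibble(x = grid, component = "negative",
           density = object$w[1] * stats::dnorm(grid, object$mu[1],
                                                sqrt(object$sigma2[1]))),
    tibble(x = grid, component = "positive",
           density = object$w[2] * stats::dnorm(grid, object$mu[2],
                                                sqrt(object$sigma2[2]))),
    tibble(x = grid, component = "mixture",
           density = object$w[1] * stats::dnorm(grid, object$mu[1],
                                                sqrt(object$sigma2[1])) +
             object$w[2] * stats::dnorm(grid, object$mu[2],
                                        sqrt(object$sigma2[2])))
  )
  p <- ggplot2::ggplot()
  if (!is.null(values)) {
    p <- p + ggplot2::geom_histogram(
      data = tibble(x = values),
      ggplot2::aes(x = .data$x, y = ggplot2::after_stat(density)),
      bins = 40, fill = "grey85", color = "grey60"
    )
  }
  p +
    ggplot2::geom_line(
      data = dens,
      ggplot2::aes(x = .data$x, y = .data$density,
                   color = .data$component, linetype = .data$component)
    ) +
    ggplot2::labs(
      x = "log2(expression + 1)", y = "density",
      title = sprintf("%s two-component mixture (%s mode)",
                      object$marker %||% "marker", object$mode)
    ) +
    ggplot2::theme_minimal()
}

#' Volcano plot of a differential result
#'
#' @param de A classified DE tibble (from [classify_de()]).
#' @param cfg A [pipeline_config()] whose gates are drawn as guide lines.
#' @return A ggplot object.
#' @export
plot_volcano <- function(de, cfg = pipeline_config()) {
  cfg <- as_pipeline_config(cfg)
  fc_col <- if ("log2fc" %in% names(de)) "log2fc" else "delta_m"
  ggplot2::ggplot(
    de,
    ggplot2::aes(x = .data[[fc_col]], y = -log10(pmax(.data$fdr, 1e-300)),
                 color = .data$status)
  ) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::geom_vline(xintercept = c(cfg$fc_down_threshold,
                                       cfg$fc_up_threshold),
                        linetype = "dashed", color = "grey50") +
    ggplot2::geom_hline(yintercept = -log10(cfg$fdr_threshold),
                        linetype = "dashed", color = "grey50") +
    ggplot2::scale_color_manual(
      values = c(up = "#c0392b", down = "#2980b9", ns = "grey70")
    ) +
    ggplot2::labs(x = "log2 fold-change", y = "-log10 FDR") +
    ggplot2::theme_minimal()
}

#' Fold-change concordance scatter plot
#'
#' @param a,b DE tibbles with `gene_id` and `log2fc`.
#' @param labels Axis labels for the two comparisons.
#' @return A ggplot object annotated with the Pearson correlation.
#' @export
plot_fc_concordance <- function(a, b, labels = c("comparison A", "comparison B")) {
  shared <- inner_join(
    a %>% select("gene_id", log2fc_a = "log2fc"),
    b %>% select("gene_id", log2fc_b = "log2fc"),
    by = "gene_id"
  )
  r <- correlate_fc(a, b)$r
  ggplot2::ggplot(shared, ggplot2::aes(x = .data$log2fc_a, y = .data$log2fc_b)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         color = "#c0392b", linewidth = 0.6) +
    ggplot2::labs(x = labels[1], y = labels[2],
                  subtitle = sprintf("Pearson r = %.3f (n = %d)", r,
                                     nrow(shared))) +
    ggplot2::theme_minimal()
}

#' Plot a binned genome track
#'
#' Expression fold-change and methylation change averaged in fixed genome
#' bins, faceted by chromosome; opposite-sign spikes indicate promoter
#' methylation anti-correlated with expression.
#'
#' @param track A binned track from [bin_genome()].
#' @return A ggplot object.
#' @export
plot_binned_track <- function(track) {
  value_cols <- setdiff(names(track), c("chrom", "bin_start", "bin_end"))
  long <- track %>%
    tidyr::pivot_longer(dplyr::all_of(value_cols), names_to = "signal",
                        values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = (.data$bin_start + .data$bin_end) / 2,
                                     y = .data$value, color = .data$signal)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::facet_wrap(~chrom, scales = "free_x") +
    ggplot2::labs(x = "genome position (bp)", y = "bin mean") +
    ggplot2::theme_minimal()
}
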