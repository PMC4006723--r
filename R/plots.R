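#' Plot a detection run: coverage, segments and called origins
#'
#' Shows binned read counts along a region, the fitted segment intensities,
#' and the called origins as a rug.
#'
#' @param object An `origin_scan` from [detect_origins()].
#' @param chrom,xlim Optional chromosome and bp range to display.
#' @param bin_size Bin width for the displayed coverage (default 2000).
#' @param profile The read-start profile used in the run (needed to re-bin
#'   for display); when omitted only segments and origins are drawn.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.origin_scan <- function(object, chrom = NULL, xlim = NULL,
                                 bin_size = 2000, profile = NULL, ...) {
  chrom <- chrom %||% object$layout$chrom[1]
  xlim <- xlim %||% c(0, object$layout$length[match(chrom,
                                                    object$layout$chrom)])
  p <- ggplot2::ggplot()
  if (!is.null(profile)) {
    bins <- bin_reads(profile, bin_size, object$layout) |>
      dplyr::filter(.data$chrom == !!chrom, .data$start >= xlim[1],
                    .data$end <= xlim[2])
    p <- p + ggplot2::geom_step(data = bins,
                                ggplot2::aes(x = .data$start,
                                             y = .data$count / bin_size),
                                color = "grey40")
  }
  segs <- dplyr::filter(object$segments, .data$chrom == !!chrom)
  p <- p +
    ggplot2::geom_segment(data = segs,
                          ggplot2::aes(x = .data$start, xend = .data$end,
                                       y = .data$lambda_hat,
                                       yend = .data$lambda_hat,
                                       color = .data$low_coverage),
                          linewidth = 1) +
    ggplot2::scale_color_manual(values = c(`FALSE` = "steelblue",
                                           `TRUE` = "tomato"),
                                name = "low coverage")
  ori <- dplyr::filter(object$origins, .data$chrom == !!chrom,
                       .data$start >= xlim[1], .data$end <= xlim[2])
  if (nrow(ori) > 0) {
    p <- p + ggplot2::geom_rect(data = ori,
                                ggplot2::aes(xmin = .data$start,
                                             xmax = .data$end,
                                             ymin = -Inf, ymax = Inf),
                                alpha = 0.15, fill = "forestgreen")
  }
  p + ggplot2::coord_cartesian(xlim = xlim) +
    ggplot2::labs(x = paste0(chrom, " position (bp)"),
                  y = "reads per bp",
                  title = "Coverage segmentation and called origins") +
    ggplot2::theme_minimal()
}

#' Plot observed vs expected feature association per stratum
#'
#' @param x Enrichment tibble from [enrichment_test()].
#' @return A ggplot object.
#' @export
plot_enrichment <- function(x) {
  ggplot2::ggplot(x, ggplot2::aes(x = factor(.data$stratum))) +
    ggplot2::geom_col(ggplot2::aes(y = .data$observed_pct,
                                   fill = .data$direction)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$expected_pct), shape = 95,
                        size = 8, color = "black") +
    ggplot2::scale_fill_manual(values = c(enriched = "firebrick",
                                          depleted = "steelblue",
                                          ns = "grey70")) +
    ggplot2::labs(x = "stratum", y = "% origins associated",
                  title = unique(x$feature),
                  subtitle = "bars: observed; dash: randomization expectation") +
    ggplot2::theme_minimal()
}

#' Plot discriminant-axis coordinates by timing group
#'
#' Scatter of the first two axes (or a per-group boxplot when a single axis
#' was fitted).
#'
#' @param object An `origin_lda` from [run_lda()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.origin_lda <- function(object, ...) {
  sc <- object$scores
  if (ncol(object$scalings) >= 2) {
    ggplot2::ggplot(sc, ggplot2::aes(x = .data$DA1, y = .data$DA2,
                                     color = .data$group)) +
      ggplot2::geom_point(alpha = 0.6) +
      ggplot2::stat_ellipse() +
      ggplot2::labs(title = "Discriminant axes of origin-to-mark distances") +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(sc, ggplot2::aes(x = .data$group, y = .data$DA1)) +
      ggplot2::geom_boxplot() +
      ggplot2::theme_minimal()
  }
}
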