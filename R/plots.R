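#' Coverage profile plot
#'
#' Depth across the genome; a single large-scale deletion at appreciable
#' heteroplasmy appears as a sharp dip between its breakpoints.
#'
#' @param profile Depth tibble from [depth_profile()].
#' @param clusters Optional cluster tibble; breakpoints are drawn as dashed
#'   verticals.
#' @return A ggplot.
#' @export
plot_coverage <- function(profile, clusters = NULL) {
  p <- ggplot2::ggplot(profile, ggplot2::aes(x = .data$pos, y = .data$depth)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "mtDNA position (bp)", y = "depth") +
    ggplot2::theme_minimal()
  if (!is.null(clusters) && nrow(clusters) > 0L) {
    p <- p + ggplot2::geom_vline(
      xintercept = c(clusters$rep_b5, clusters$rep_b3),
      linetype = "dashed", colour = "firebrick", linewidth = 0.3
    )
  }
  p
}

#' Circular arc plot of deletion clusters
#'
#' A circos-style view: the genome on the unit circle, each deletion
#' cluster as a chord between its breakpoints, line width scaled by read
#' support.
#'
#' @param clusters Cluster tibble from [cluster_deletions()].
#' @param L Genome length.
#' @return A ggplot.
#' @export
plot_deletion_arcs <- function(clusters, L = 16569L) {
  ang <- function(p) 2 * pi * (p - 1) / L
  circle <- tibble::tibble(
    x = cos(ang(seq(1, L, length.out = 361))),
    y = sin(ang(seq(1, L, length.out = 361)))
  )
  p <- ggplot2::ggplot() +
    ggplot2::geom_path(data = circle, ggplot2::aes(.data$x, .data$y),
                       colour = "grey40") +
    ggplot2::coord_equal() +
    ggplot2::theme_void()
  if (nrow(clusters) > 0L) {
    chords <- dplyr::mutate(
      dplyr::select(clusters, -dplyr::any_of("members")),
      x = cos(ang(.data$rep_b5)), y = sin(ang(.data$rep_b5)),
      xend = cos(ang(.data$rep_b3)), yend = sin(ang(.data$rep_b3))
    )
    p <- p + ggplot2::geom_segment(
      data = chords,
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend,
                   yend = .data$yend, linewidth = .data$support,
                   colour = .data$recurrent)
    ) +
      ggplot2::scale_linewidth(range = c(0.3, 2)) +
      ggplot2::labs(linewidth = "reads", colour = "recurrent")
  }
  p
}

#' Microhomology length histogram
#'
#' @param histogram `histogram` element of [homology_summary()].
#' @return A ggplot of microhomology-length frequencies per source.
#' @export
plot_microhomology <- function(histogram) {
  ggplot2::ggplot(histogram,
                  ggplot2::aes(x = .data$mh_len, y = .data$freq,
                               fill = .data$source)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "microhomology length (bp)", y = "frequency") +
    ggplot2::theme_minimal()
}

#' Bland-Altman plot
#'
#' @param object A [bland_altman()] result.
#' @param ... Unused.
#' @return A ggplot: per-sample differences against means, with bias and
#'   limits of agreement.
#' @exportS3Method ggplot2::autoplot
autoplot.bland_altman <- function(object, ...) {
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$mean_pct, y = .data$diff_pct)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = object$bias, colour = "steelblue") +
    ggplot2::geom_hline(yintercept = c(object$loa_low, object$loa_high),
                        linetype = "dashed", colour = "grey40") +
    ggplot2::labs(x = "mean of LRS and ddPCR (%)",
                  y = "LRS - ddPCR (%)") +
    ggplot2::theme_minimal()
}

#' Downsampling precision plot
#'
#' @param series Output of [downsample_series()].
#' @return A ggplot of heteroplasmy per replicate against mean coverage.
#' @export
plot_downsampling <- function(series) {
  ggplot2::ggplot(series,
                  ggplot2::aes(x = .data$mean_cov, y = .data$heteroplasmy)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::labs(x = "mean coverage (x)", y = "heteroplasmy (%)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
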