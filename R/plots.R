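#' Heatmap of an electrostatic distance matrix
#'
#' Rows/columns ordered by average-linkage hierarchical clustering on D
#' (the conventional similarity-analysis presentation); set
#' `cluster = FALSE` to keep time order.
#'
#' @param object an `esp_distmat`.
#' @param cluster reorder by average-linkage clustering.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.esp_distmat <- function(object, cluster = TRUE, ...) {
  D <- object$D
  ord <- seq_len(nrow(D))
  if (cluster && nrow(D) > 2)
    ord <- hclust(as.dist(D), method = "average")$order
  lv <- object$labels[ord]
  df <- tidyr::expand_grid(a = lv, b = lv)
  df$distance <- D[cbind(match(df$a, object$labels),
                         match(df$b, object$labels))]
  df$a <- factor(df$a, levels = lv)
  df$b <- factor(df$b, levels = lv)
  ggplot2::ggplot(df, ggplot2::aes(.data$a, .data$b,
                                   fill = .data$distance)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "D", limits = c(0, NA)) +
    ggplot2::labs(x = NULL, y = NULL,
                  title = "Electrostatic distance (skin region)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Histogram of ensemble bulge heights
#'
#' @param heights numeric vector of bulge heights (A), or a tibble from
#'   [bulge_heights()].
#' @param binwidth histogram bin width (A).
#' @return a ggplot object.
#' @export
plot_bulge_distribution <- function(heights, binwidth = 0.25) {
  if (is.data.frame(heights)) heights <- heights$bulge_height
  df <- tibble::tibble(height = heights[!is.na(heights)])
  ggplot2::ggplot(df, ggplot2::aes(.data$height)) +
    ggplot2::geom_histogram(binwidth = binwidth, fill = "grey40",
                            color = "white") +
    ggplot2::labs(x = "isopotential bulge height (Å)", y = "count") +
    ggplot2::theme_minimal()
}

#' Density map of headgroup tilt angles
#'
#' @param geom tibble with `theta` and `phi` columns (see
#'   [geometry_table()]).
#' @return a ggplot object.
#' @export
plot_tilt_density <- function(geom) {
  ggplot2::ggplot(geom, ggplot2::aes(.data$theta, .data$phi)) +
    ggplot2::geom_density_2d(color = "red") +
    ggplot2::geom_point(alpha = 0.3, size = 0.6) +
    ggplot2::labs(x = expression(Theta ~ "(deg)"),
                  y = expression(Phi ~ "(deg)")) +
    ggplot2::theme_minimal()
}

#' Autocorrelation plot of the electrostatic distance
#'
#' @param acf_tbl tibble from [distance_autocorrelation()].
#' @return a ggplot object.
#' @export
plot_distance_acf <- function(acf_tbl) {
  ggplot2::ggplot(acf_tbl, ggplot2::aes(.data$lag_ns, .data$acf)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, color = "grey60") +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "lag (ns)", y = "ACF") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
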