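#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a raster with ggplot2
#'
#' Categorical rasters are drawn with their legend names; continuous
#' rasters with a viridis gradient.
#'
#' @param object An `hs_raster`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.hs_raster <- function(object, ...) {
  df <- as_tibble.hs_raster(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
  if (inherits(object, "hs_cat_raster")) {
    p + ggplot2::geom_raster(ggplot2::aes(fill = .data$class)) +
      ggplot2::scale_fill_brewer(palette = "Set2", name = NULL)
  } else {
    p + ggplot2::geom_raster(ggplot2::aes(fill = .data$value)) +
      ggplot2::scale_fill_viridis_c(name = NULL)
  }
}

#' Plot a habitat-quality surface
#' @param object An `hs_quality`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.hs_quality <- function(object, ...) {
  autoplot.hs_raster(object$quality) +
    ggplot2::scale_fill_viridis_c(name = "Q", limits = c(0, 1))
}

#' Plot quality-vs-metric correlations
#'
#' Bar chart of Pearson r per landscape metric, marking significance at
#' the 0.05 level.
#'
#' @param object An `hs_correlation` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.hs_correlation <- function(object, ...) {
  df <- dplyr::mutate(
    tibble::as_tibble(object),
    metric = toupper(.data$metric),
    significant = !is.na(.data$p) & .data$p < 0.05
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$metric, y = .data$r,
                                   fill = .data$significant)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = 0) +
    ggplot2::ylim(-1, 1) +
    ggplot2::labs(x = NULL, y = "Pearson r",
                  fill = "p < 0.05") +
    ggplot2::theme_minimal()
}
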