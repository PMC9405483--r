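# ggplot2 views of detection and morphometry results.

#' Plot a detection result over its stack projection
#'
#' Maximum-intensity projection of the counted channel with cell-track
#' centroids and accepted debris marked.
#'
#' @param object A `detection_result`.
#' @param stack The [zstack()] the result came from.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.detection_result <- function(object, stack, ...) {
  proj <- max_projection(stack, object$channel)
  cal <- object$calibration
  df <- tibble::tibble(
    x = rep(px_centers_x(ncol(proj), cal), each = nrow(proj)),
    y = rep(px_centers_y(nrow(proj), cal), times = ncol(proj)),
    value = as.vector(proj))
  cells <- dplyr::filter(object$tracks, .data$is_cell)
  deb <- dplyr::filter(object$debris, .data$accepted)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$value)) +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 guide = "none") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (µm)", y = "y (µm)",
                  title = sprintf("%s: %d cells, %d debris", object$channel,
                                  object$n_cells, object$n_debris)) +
    ggplot2::theme_minimal()
  if (nrow(cells)) {
    p <- p + ggplot2::geom_point(
      data = cells,
      ggplot2::aes(x = .data$centroid_x_um, y = .data$centroid_y_um),
      colour = "yellow", shape = 1, size = 3)
  }
  if (nrow(deb)) {
    p <- p + ggplot2::geom_point(
      data = deb,
      ggplot2::aes(x = .data$centroid_x_um, y = .data$centroid_y_um),
      colour = "cyan", shape = 4, size = 2)
  }
  p
}

#' Plot a thickness profile
#'
#' Per-column band thickness along the ROI with the mean marked.
#'
#' @param object A `thickness_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.thickness_result <- function(object, ...) {
  df <- dplyr::filter(object$profile, !is.na(.data$thickness_um))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x_um, y = .data$thickness_um)) +
    ggplot2::geom_line(colour = "grey50") +
    ggplot2::geom_hline(yintercept = object$mean_um, colour = "steelblue") +
    ggplot2::labs(x = "x (µm)", y = "band thickness (µm)",
                  title = if (object$flagged) "flagged: band sparse"
                  else sprintf("mean %.1f µm", object$mean_um)) +
    ggplot2::theme_minimal()
}
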