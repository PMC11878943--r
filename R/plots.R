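#' Plot a synthetic scene with its annotations
#'
#' Renders the scene image and overlays the tight bounding boxes, coloured
#' by class (MP = parturition, MNP = non-parturition). Detections can be
#' overlaid for visual comparison.
#'
#' @param scene A `synthetic_scene` from [generate_scene()].
#' @param detections Optional tibble (`x, y, w, h, label`, optional
#'   `score`) drawn with dashed borders.
#' @return A ggplot object.
#' @export
plot_scene <- function(scene, detections = NULL) {
  img <- scene$image
  h <- dim(img)[1L]; w <- dim(img)[2L]
  raster <- grDevices::as.raster(img)
  boxes <- scene$boxes
  boxes$label <- scene$labels
  p <- ggplot2::ggplot() +
    ggplot2::annotation_raster(raster, xmin = 0, xmax = w, ymin = 0,
                               ymax = h) +
    ggplot2::scale_y_reverse(limits = c(h, 0), expand = c(0, 0)) +
    ggplot2::scale_x_continuous(limits = c(0, w), expand = c(0, 0)) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL, colour = NULL)
  if (nrow(boxes) > 0L) {
    p <- p + ggplot2::geom_rect(
      data = boxes,
      ggplot2::aes(xmin = .data$x, xmax = .data$x + .data$w,
                   ymin = .data$y, ymax = .data$y + .data$h,
                   colour = .data$label),
      fill = NA, linewidth = 0.6)
  }
  if (!is.null(detections) && nrow(detections) > 0L) {
    p <- p + ggplot2::geom_rect(
      data = detections,
      ggplot2::aes(xmin = .data$x, xmax = .data$x + .data$w,
                   ymin = .data$y, ymax = .data$y + .data$h,
                   colour = .data$label),
      fill = NA, linetype = "dashed", linewidth = 0.5)
  }
  p
}
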