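raster_df <- function(img) {
  tibble(
    x = as.vector(col(img)),
    y = as.vector(row(img)),
    value = as.vector(img)
  )
}

gg_raster <- function(img, legend = "intensity") {
  ggplot2::ggplot(raster_df(img), ggplot2::aes(.data$x, .data$y,
                                               fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white", name = legend) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed(expand = FALSE) +
    ggplot2::theme_minimal()
}

#' Plot a synthetic scene
#'
#' Renders the micrograph with ground-truth cells circled (live solid, dead
#' dashed; cluster members in yellow).
#'
#' @param object A `foa_scene`.
#' @param show_gt Overlay ground-truth markers.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.foa_scene <- function(object, show_gt = TRUE, ...) {
  p <- gg_raster(scene_image(object), legend = "gray")
  if (show_gt && nrow(object$gt) > 0) {
    p <- p + ggplot2::geom_point(
      data = object$gt,
      ggplot2::aes(.data$x, .data$y, color = .data$label,
                   shape = .data$cluster_member),
      inherit.aes = FALSE, size = 3, stroke = 1.1
    ) +
      ggplot2::scale_color_manual(values = c(live = "red", dead = "blue")) +
      ggplot2::scale_shape_manual(values = c(`FALSE` = 1, `TRUE` = 0),
                                  name = "cluster")
  }
  p
}

#' Plot a score map
#'
#' @param object A `foa_score_map` from [score_live()] or [score_dead()].
#' @param ... Unused.
#' @return A ggplot; invalid border positions are blank.
#' @export
autoplot.foa_score_map <- function(object, ...) {
  df <- raster_df(object$scores)
  df <- df[!is.na(df$value), , drop = FALSE]
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = paste(object$mode, "score")) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed(expand = FALSE) +
    ggplot2::theme_minimal()
}

#' Plot detections over an image
#'
#' @param img Grayscale matrix the detections refer to.
#' @param detections A `foa_detections` object or combined tibble.
#' @return A ggplot with live detections in red, dead in blue.
#' @export
plot_detections <- function(img, detections) {
  if (inherits(detections, "foa_detections")) {
    detections <- detections_table(detections)
  }
  gg_raster(img, legend = "gray") +
    ggplot2::geom_point(
      data = detections,
      ggplot2::aes(.data$x, .data$y, color = .data$label),
      inherit.aes = FALSE, shape = 3, size = 3, stroke = 1.2
    ) +
    ggplot2::scale_color_manual(values = c(live = "red", dead = "blue"))
}

#' Plot per-fold cross-validation rates
#'
#' @param object A `foa_cv` from [kfold_evaluate()].
#' @param ... Unused.
#' @return A ggplot of per-fold live/dead identification percentages.
#' @export
autoplot.foa_cv <- function(object, ...) {
  df <- tidyr::pivot_longer(
    object$folds[, c("fold", "live_rate_pct", "dead_rate_pct")],
    cols = -"fold", names_to = "class", values_to = "rate_pct")
  df$class <- sub("_rate_pct", "", df$class)
  ggplot2::ggplot(df, ggplot2::aes(factor(.data$fold), .data$rate_pct,
                                   fill = .data$class)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_fill_manual(values = c(live = "red", dead = "blue")) +
    ggplot2::labs(x = "fold", y = "identification rate (%)") +
    ggplot2::coord_cartesian(ylim = c(0, 100)) +
    ggplot2::theme_minimal()
}
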