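#' @export
autoplot.swarm_trajectory <- function(object, step = max(object$frames$step),
                                      ...) {
  df <- object$frames[object$frames$step == step, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(size = 0.4, alpha = 0.6) +
    ggplot2::coord_equal() +
    ggplot2::labs(title = sprintf("swarm at step %d", step),
                  x = "x (model units)", y = "y (model units)")
}

#' @export
autoplot.swarm_raster <- function(object, ...) {
  org <- attr(object, "origin"); cs <- attr(object, "cell_size")
  df <- expand.grid(iy = seq_len(nrow(object)), ix = seq_len(ncol(object)))
  df$x <- org[1] + (df$ix - 0.5) * cs
  df$y <- org[2] + (df$iy - 0.5) * cs
  df$value <- as.vector(unclass(object))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(na.value = "black") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x", y = "y")
}

#' @export
autoplot.kymograph <- function(object, ...) {
  steps <- attr(object, "steps"); pos <- attr(object, "positions")
  df <- expand.grid(row = seq_len(nrow(object)), col = seq_len(ncol(object)))
  df$step <- steps[df$row]
  df$position <- pos[df$col]
  df$value <- as.vector(unclass(object))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = .data$step,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +     # time runs downward, first frame on top
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "position along line", y = "step")
}

#' Plot cluster tracks coloured by classification
#'
#' @param classified Output of [classify_tracks()].
#' @return A ggplot object.
#' @export
plot_tracks <- function(classified) {
  ggplot2::ggplot(classified,
                  ggplot2::aes(x = .data$cx, y = .data$cy,
                               group = .data$track, colour = .data$label)) +
    ggplot2::geom_path(alpha = 0.7) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x", y = "y", colour = "state")
}

#' @export
autoplot.piv_field <- function(object, scale = 1, ...) {
  v <- object[object$valid, ]
  ggplot2::ggplot(v, ggplot2::aes(x = .data$cx, y = .data$cy)) +
    ggplot2::geom_segment(
      ggplot2::aes(xend = .data$cx + scale * .data$dx,
                   yend = .data$cy + scale * .data$dy),
      arrow = ggplot2::arrow(length = ggplot2::unit(0.1, "cm"))) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (px)", y = "y (px)")
}
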