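#' Plot a TPI curve
#'
#' Transfer potential against transfer point, with the accuracy-potential
#' and cost-level components.
#'
#' @param object A `tpi_curve`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.tpi_curve <- function(object, ...) {
  df <- tibble(
    x = rep(object$x, 2L),
    value = c(object$tpi, object$tpi_wks),
    series = rep(c("TPI", "accuracy potential (WKs)"),
                 each = nrow(object))
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$value,
                                   colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "transfer point (frozen depth)", y = NULL,
                  colour = NULL,
                  title = attr(object, "dataset") %||% NULL) +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' Plot a training trace
#'
#' @param object A `train_trace`.
#' @param ... Unused.
#' @return A ggplot of the per-iteration loss.
#' @export
autoplot.train_trace <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$iteration, y = .data$loss)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "iteration", y = "weighted cross-entropy") +
    ggplot2::theme_minimal()
}

#' Display a scene
#'
#' Renders the RGB image or the palette-coded label of a scene.
#'
#' @param scene A scene.
#' @param what `"image"` or `"label"`.
#' @return A ggplot.
#' @export
plot_scene <- function(scene, what = c("image", "label")) {
  what <- match.arg(what)
  raster <- if (what == "image") scene$image else encode_label(scene$label)
  h <- dim(raster)[1]
  w <- dim(raster)[2]
  cols <- grDevices::rgb(raster[, , 1], raster[, , 2], raster[, , 3],
                         maxColorValue = 255)
  df <- tibble(
    row = rep(seq_len(h), times = w),
    col = rep(seq_len(w), each = h),
    fill = cols
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$fill)) +
    ggplot2::scale_fill_identity() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::theme_void()
}

#' Plot sweep results
#'
#' Final target WKs (or iterations to convergence) across the TP and TDS
#' sweep grids.
#'
#' @param sweep Tibble from [run_sweep()].
#' @param y `"wks"` or `"converged_at"`.
#' @return A ggplot faceted by sweep kind.
#' @export
plot_sweep <- function(sweep, y = c("wks", "converged_at")) {
  y <- match.arg(y)
  df <- dplyr::mutate(sweep,
                      grid = ifelse(.data$sweep == "tp", .data$tp, .data$tds))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$grid, y = .data[[y]],
                                   group = factor(.data$seed),
                                   colour = factor(.data$seed))) +
    ggplot2::geom_line(alpha = 0.6) +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~sweep, scales = "free_x") +
    ggplot2::labs(x = NULL, colour = "seed") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
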