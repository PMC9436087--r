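#' Plot methods
#'
#' `autoplot()` turns results into ggplot2 figures: the AP-vs-IoU-threshold
#' curve of an evaluation, the per-method AP distribution of a benchmark, or
#' a labelled central slice of a segmentation. `plot_slice()` draws one
#' z-slice of any volume.
#'
#' @param object an `sxt_eval`, `sxt_benchmark` or `sxt_instances` object.
#' @param ... unused.
#' @return a ggplot object.
#' @name sxtseg-plots
NULL

#' @rdname sxtseg-plots
#' @export
autoplot.sxt_eval <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$iou_threshold, y = .data$ap)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "IoU threshold", y = "AP (%)",
                  title = sprintf("mAP %.1f%%", object$map)) +
    ggplot2::ylim(0, 100) +
    ggplot2::theme_minimal()
}

#' @rdname sxtseg-plots
#' @export
autoplot.sxt_benchmark <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$method, y = .data$map)) +
    ggplot2::geom_boxplot() +
    ggplot2::labs(x = NULL, y = "mAP (%) per dataset",
                  title = sprintf("%s benchmark", attr(object, "morphology"))) +
    ggplot2::theme_minimal()
}

#' @rdname sxtseg-plots
#' @export
autoplot.sxt_instances <- function(object, ...) {
  plot_slice(object$mask)
}

#' Plot one z-slice of a volume
#'
#' @param vol an `sxt_volume`.
#' @param z slice index (defaults to the middle slice).
#' @return a ggplot object: intensity raster for tomograms, discrete label
#'   raster for masks.
#' @export
plot_slice <- function(vol, z = NULL) {
  d <- dim(vol)
  if (is.null(z)) z <- ceiling(d[1] / 2)
  sl <- as_bare_array(vol)[z, , , drop = TRUE]
  dim(sl) <- d[2:3]
  df <- expand.grid(y = seq_len(d[2]), x = seq_len(d[3]))
  df$value <- as.vector(sl)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y))
  if (inherits(vol, "tomogram")) {
    p <- p + ggplot2::geom_raster(ggplot2::aes(fill = .data$value)) +
      ggplot2::scale_fill_viridis_c(name = "intensity")
  } else {
    df$label <- factor(df$value)
    p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
      ggplot2::geom_raster(ggplot2::aes(fill = .data$label)) +
      ggplot2::scale_fill_viridis_d(name = "label")
  }
  p + ggplot2::coord_fixed() +
    ggplot2::labs(title = sprintf("z = %d", z)) +
    ggplot2::theme_minimal()
}
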