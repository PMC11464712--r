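#' Plot a pennation-angle map
#'
#' Raster view of the per-voxel pennation angle (degrees) on the
#' annotation slice, with the tendon direction implicit in the color
#' origin (0 deg = fiber parallel to the tendon projection).
#'
#' @param object A `pa_map`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pa_map
#' @export
autoplot.pa_map <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$i, y = .data$j, fill = .data$pa)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "PA (deg)", limits = c(0, 90), na.value = "grey90") +
    ggplot2::coord_fixed() +
    ggplot2::labs(
      x = "in-plane voxel (axis 1)", y = "in-plane voxel (axis 2)",
      title = sprintf("Pennation-angle map, slice %d", object$slice)
    ) +
    ggplot2::theme_minimal()
}

#' @export
plot.pa_map <- function(x, ...) print(autoplot(x, ...))

#' @export
tidy.pa_map <- function(x, ...) {
  d <- dim(x$pa)
  tibble::tibble(
    i = rep(seq_len(d[1]), d[2]),
    j = rep(seq_len(d[2]), each = d[1]),
    pa = as.numeric(x$pa)
  )
}

#' @export
glance.pa_map <- function(x, ...) {
  v <- x$pa[is.finite(x$pa)]
  tibble::tibble(
    slice = x$slice, n_finite = length(v),
    mean_pa = if (length(v)) mean(v) else NA_real_,
    sd_pa = if (length(v) > 1) sd(v) else NA_real_
  )
}

#' Plot streamlines projected onto an anatomical plane
#'
#' @param object A `streamline_set`.
#' @param axes Which world axes to draw (default c(1, 2), the axial
#'   projection).
#' @param max_streamlines Subsample cap for plotting speed.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot streamline_set
#' @export
autoplot.streamline_set <- function(object, axes = c(1, 2), max_streamlines = 500, ...) {
  sl <- object$streamlines
  if (length(sl) > max_streamlines) sl <- sl[seq_len(max_streamlines)]
  df <- dplyr::bind_rows(lapply(seq_along(sl), function(i) {
    tibble::tibble(id = i, x = sl[[i]][, axes[1]], y = sl[[i]][, axes[2]],
                   length_mm = object$lengths[i])
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   group = .data$id, color = .data$length_mm)) +
    ggplot2::geom_path(alpha = 0.6, linewidth = 0.3) +
    ggplot2::scale_color_viridis_c(name = "length (mm)") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = sprintf("world axis %d (mm)", axes[1]),
                  y = sprintf("world axis %d (mm)", axes[2])) +
    ggplot2::theme_minimal()
}

#' @export
plot.streamline_set <- function(x, ...) print(autoplot(x, ...))

#' @export
tidy.streamline_set <- function(x, ...) {
  tibble::tibble(id = seq_along(x$streamlines),
                 n_points = vapply(x$streamlines, nrow, integer(1)),
                 length_mm = x$lengths)
}

#' Forest-style plot of a reliability report
#'
#' @param report Tibble from [reliability_report].
#' @return A ggplot object.
#' @export
plot_reliability <- function(report) {
  report$label <- paste(report$design, report$stratum, sep = ": ")
  ggplot2::ggplot(report, ggplot2::aes(x = .data$estimate, y = .data$label,
                                       color = .data$design)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$conf_low, xmax = .data$conf_high), height = 0.2) +
    ggplot2::geom_vline(xintercept = c(0.5, 0.75, 0.9), linetype = "dashed",
                        color = "grey60") +
    ggplot2::xlim(min(0, min(report$conf_low)), 1) +
    ggplot2::labs(x = "ICC (absolute agreement)", y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}
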