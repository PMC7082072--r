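#' Plot a cone mosaic colored by class or fate
#'
#' @param object A [cell_table()].
#' @param color `"class_label"` or `"fate_truth"`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cell_table <- function(object, color = c("class_label", "fate_truth"),
                                ...) {
  color <- match.arg(color)
  ggplot2::ggplot(
    object,
    ggplot2::aes(.data$y_um, .data$x_um, colour = .data[[color]])
  ) +
    ggplot2::geom_point(size = 0.3) +
    ggplot2::coord_fixed() +
    ggplot2::labs(
      x = "D-V position (µm, dorsal at 0)", y = "T-N position (µm)",
      colour = NULL
    ) +
    ggplot2::theme_minimal()
}

#' Plot a D-V fraction or intensity profile
#'
#' @param profile A [fraction_profile()] or [intensity_profile()] tibble.
#' @param fit Optional [fit_hill()] overlay.
#' @return A ggplot.
#' @export
plot_profile <- function(profile, fit = NULL) {
  val_col <- if ("fraction" %in% names(profile)) "fraction" else "mean_intensity"
  p <- ggplot2::ggplot(
    dplyr::filter(profile, !.data$empty),
    ggplot2::aes(.data$bin_center_um, .data[[val_col]])
  ) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "D-V position (µm)", y = val_col) +
    ggplot2::theme_minimal()
  if (!is.null(fit)) {
    grid <- tibble(bin_center_um = seq(
      min(profile$bin_center_um), max(profile$bin_center_um),
      length.out = 300
    ))
    grid[[val_col]] <- predict(fit, grid$bin_center_um)
    p <- p + ggplot2::geom_line(data = grid, colour = "#b2182b")
  }
  p
}

#' Plot clustering of the expression plane
#'
#' @param table The clustered [cell_table()].
#' @param clusters A [cluster_cells()] result for the same table.
#' @return A ggplot.
#' @export
plot_clusters <- function(table, clusters) {
  stopifnot(length(clusters$labels) == nrow(table))
  df <- dplyr::mutate(
    tibble::as_tibble(table),
    cluster = factor(clusters$labels)
  )
  ggplot2::ggplot(
    df,
    ggplot2::aes(.data$s_intensity, .data$m_intensity, colour = .data$cluster)
  ) +
    ggplot2::geom_point(size = 0.4, alpha = 0.5) +
    ggplot2::labs(
      x = "S-opsin intensity (a.u.)", y = "M-opsin intensity (a.u.)",
      colour = "cluster"
    ) +
    ggplot2::theme_minimal()
}

#' Plot a T3 field
#'
#' @param field An [init_t3_field()] / [step_field()] matrix.
#' @return A ggplot.
#' @export
plot_t3_field <- function(field) {
  h <- attr(field, "grid_spacing_um") %||% 1
  df <- tidyr::expand_grid(
    row = seq_len(nrow(field)), col = seq_len(ncol(field))
  )
  df$c <- as.vector(unclass(field))[(df$col - 1) * nrow(field) + df$row]
  ggplot2::ggplot(df, ggplot2::aes((.data$row - 1) * h, (.data$col - 1) * h,
    fill = .data$c
  )) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "[T3] (rel.)") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "D-V position (µm)", y = "T-N position (µm)") +
    ggplot2::theme_minimal()
}
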