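# ggplot2 display helpers.

.raster_df <- function(m, value_name = "value") {
  tibble::tibble(
    row = as.vector(row(m)),
    col = as.vector(col(m)),
    value = as.vector(m)
  )
}

#' @exportS3Method ggplot2::autoplot
autoplot.mip_image <- function(object, ...) {
  df <- .raster_df(object$pixels)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 name = "intensity") +
    ggplot2::coord_equal() +
    ggplot2::labs(title = object$case_id, x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.vesselness_map <- function(object, ...) {
  df <- .raster_df(object$values)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(name = "vesselness", limits = c(0, 1)) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Overlay phantom ground-truth masks on the image
#'
#' @param phantom A phantom from [generate_phantom()].
#' @return A ggplot object.
#' @export
plot_phantom <- function(phantom) {
  df <- .raster_df(phantom$image$pixels)
  overlay <- dplyr::bind_rows(
    dplyr::mutate(.raster_df(phantom$tumor_mask_gt$pixels), mask = "tumor"),
    dplyr::mutate(.raster_df(phantom$vessel_mask_gt$pixels), mask = "vessel")
  ) |> dplyr::filter(.data$value > 0)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$value)) +
    ggplot2::geom_point(data = overlay,
                        ggplot2::aes(colour = .data$mask),
                        size = 0.1, alpha = 0.4) +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 name = "intensity") +
    ggplot2::coord_equal() +
    ggplot2::labs(title = sprintf("%s (label %d)", phantom$image$case_id,
                                  phantom$label),
                  x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}
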