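#' Plot a centerline path
#'
#' Planar projections (x-z, y-z) of the path stations, coloured by arc
#' length.
#'
#' @param object a `centerline_path`.
#' @param ... unused.
#' @method autoplot centerline_path
#' @export
autoplot.centerline_path <- function(object, ...) {
  df <- tidy(object)
  long <- tidyr::pivot_longer(df, c("x", "y"), names_to = "axis",
                              values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$value, y = .data$z,
                                     colour = .data$s_mm)) +
    ggplot2::geom_path() +
    ggplot2::facet_wrap(~axis, scales = "free_x") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "mm", y = "z (mm)", colour = "arc length (mm)") +
    ggplot2::theme_minimal()
}
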