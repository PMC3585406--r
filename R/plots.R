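# ggplot2 visualizations for the main result types.

#' @exportS3Method ggplot2::autoplot
autoplot.selection_report <- function(object, ...) {
  df <- object$stages
  df$stage <- factor(df$stage, levels = df$stage)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$stage, y = .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), vjust = -0.4, size = 3) +
    ggplot2::labs(x = NULL, y = "candidate sites",
                  title = "Mutation selection cascade") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' @exportS3Method ggplot2::autoplot
autoplot.mode_set <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mode, y = .data$eigenvalue,
                                   color = .data$rigid_body)) +
    ggplot2::geom_point() +
    ggplot2::scale_color_manual(values = c(`FALSE` = "black", `TRUE` = "firebrick"),
                                name = "rigid body") +
    ggplot2::labs(x = "mode index", y = "eigenvalue (gamma units)",
                  title = "ANM spectrum") +
    ggplot2::theme_minimal()
}

#' @param slice Axis-perpendicular slice index (default: middle z plane).
#' @rdname autoplot.selection_report
#' @exportS3Method ggplot2::autoplot
autoplot.potential_grid <- function(object, slice = NULL, ...) {
  k <- slice %||% ceiling(object$dims[3] / 2)
  ax <- grid_axes(object)
  df <- tidyr::expand_grid(x = ax[[1]], y = ax[[2]])
  df$phi <- as.vector(t(object$values[, , k]))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y, fill = .data$phi)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "red", mid = "white", high = "blue",
                                  name = "phi (kT/e)") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (A)", y = "y (A)",
                  title = sprintf("potential slice z = %.1f A", ax[[3]][k])) +
    ggplot2::theme_minimal()
}

#' Plot column profiles as stacked residue frequencies
#'
#' @param profiles Tibble from [column_profiles()] or
#'   [fixture_bundle()]`("table1_profiles")`.
#' @return A ggplot object.
#' @export
plot_profiles <- function(profiles) {
  ggplot2::ggplot(profiles,
                  ggplot2::aes(x = factor(.data$site), y = .data$freq,
                               fill = .data$residue)) +
    ggplot2::geom_col(color = "grey30", linewidth = 0.2) +
    ggplot2::labs(x = "site", y = "frequency", fill = "residue",
                  title = "Homolog column profiles") +
    ggplot2::theme_minimal()
}
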