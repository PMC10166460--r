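#' Heatmap of a window-pair matrix
#'
#' Generic ggplot2 heatmap for any of the package's symmetric window-pair
#' matrices (microhomology scores, repeat densities, duplex energies,
#' imported contact matrices).
#'
#' @param m A square matrix on a window grid.
#' @param grid Optional [build_grid()] result; if supplied, axes are in bp
#'   (window centers) rather than window indices.
#' @param name Fill-scale label.
#' @return A ggplot object.
#' @export
plot_window_matrix <- function(m, grid = attr(m, "grid"),
                               name = "value") {
  n <- nrow(m)
  ax <- if (!is.null(grid)) grid$center else seq_len(n)
  df <- tidyr::expand_grid(i = seq_len(n), j = seq_len(n))
  df$x <- ax[df$i]
  df$y <- ax[df$j]
  df$value <- m[cbind(df$i, df$j)]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = name, na.value = "grey90") +
    ggplot2::labs(x = if (is.null(grid)) "window i" else "position (bp)",
                  y = if (is.null(grid)) "window j" else "position (bp)") +
    ggplot2::coord_fixed() +
    ggplot2::theme_minimal()
}

#' @export
autoplot.contact_scan <- function(object, ...) {
  p <- plot_window_matrix(object$aic_surface, object$grid, name = "AIC")
  b <- object$best
  ax <- object$grid$center
  p + ggplot2::annotate("point", x = ax[b$i], y = ax[b$j],
                        shape = 4, size = 3, colour = "red")
}

#' @export
autoplot.center_dispersion <- function(object, ...) {
  df <- tibble::tibble(replicate_sd = object$replicate_sds)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$replicate_sd)) +
    ggplot2::geom_histogram(bins = 50, fill = "grey70", colour = NA) +
    ggplot2::geom_vline(xintercept = object$observed_sd,
                        colour = "red", linetype = 2) +
    ggplot2::labs(x = "replicate SD of deletion centers (bp)", y = "count",
                  subtitle = paste0("one-sided p = ",
                                    format(object$p_value))) +
    ggplot2::theme_minimal()
}

#' Scatter plot of clustered deletion breakpoints
#'
#' @param clustered Output of [cluster_breakpoints()].
#' @return A ggplot object; noise points are grey.
#' @export
plot_breakpoint_clusters <- function(clustered) {
  df <- dplyr::mutate(clustered,
                      label = factor(ifelse(.data$cluster == 0L, "noise",
                                            paste0("c", .data$cluster))))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$del5, y = .data$del3,
                                   colour = .data$label)) +
    ggplot2::geom_point(alpha = 0.7, size = 1) +
    ggplot2::labs(x = "5' breakpoint (bp)", y = "3' breakpoint (bp)",
                  colour = "cluster") +
    ggplot2::theme_minimal()
}
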