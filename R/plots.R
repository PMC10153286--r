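# ggplot2 visualizations for the field containers and result tables.

field_df <- function(values, pixel_size) {
  n <- nrow(values)
  xs <- pixel_centers(n, pixel_size)
  tibble::tibble(
    x = rep(xs, times = n),
    y = rep(xs, each = n),
    value = as.vector(values)
  )
}

#' @export
autoplot.cell_geometry <- function(object, ...) {
  df <- field_df(object$indicator, object$pixel_size)
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = factor(.data$value))) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_manual(values = c(`0` = "grey95", `1` = "steelblue"),
                               guide = "none") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (µm)", y = "y (µm)",
                  title = "Colony indicator") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.stiffness_field <- function(object, ...) {
  df <- field_df(object$values / 1000, object$pixel_size)
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "E_s (kPa)", na.value = "grey90") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (µm)", y = "y (µm)",
                  title = sprintf("Substrate stiffness (%s)", object$mode)) +
    ggplot2::theme_minimal()
}

#' Plot a traction field
#'
#' Magnitude heatmap with optionally overlaid, subsampled traction vectors.
#'
#' @param object A [traction_field()].
#' @param arrows Overlay direction arrows.
#' @param arrow_step Subsampling stride for arrows (pixels).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.traction_field <- function(object, arrows = FALSE, arrow_step = 6L,
                                    ...) {
  mag <- traction_magnitude(object)
  df <- field_df(mag, object$pixel_size)
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "|T| (Pa)", option = "inferno") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (µm)", y = "y (µm)",
                  title = "Traction magnitude") +
    ggplot2::theme_minimal()
  if (arrows) {
    n <- object$n
    keep <- seq(1L, n, by = arrow_step)
    xs <- pixel_centers(n, object$pixel_size)
    adf <- expand.grid(i = keep, j = keep)
    adf$x <- xs[adf$i]; adf$y <- xs[adf$j]
    adf$tx <- object$components[, , 1][cbind(adf$i, adf$j)]
    adf$ty <- object$components[, , 2][cbind(adf$i, adf$j)]
    adf <- adf[sqrt(adf$tx^2 + adf$ty^2) > 0.05 * max(mag), ]
    sc <- arrow_step * object$pixel_size / max(mag)
    p <- p + ggplot2::geom_segment(
      data = adf,
      ggplot2::aes(x = .data$x, y = .data$y,
                   xend = .data$x + .data$tx * sc,
                   yend = .data$y + .data$ty * sc),
      inherit.aes = FALSE, colour = "white", linewidth = 0.3,
      arrow = ggplot2::arrow(length = ggplot2::unit(1.2, "mm"))
    )
  }
  p
}

#' @export
autoplot.durotaxis_report <- function(object, ...) {
  df <- field_df(object$delta_t_x, object$pixel_size)
  lim <- max(abs(df$value))
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(name = "ΔT_x (Pa)",
                                  low = "navy", high = "firebrick",
                                  limits = c(-lim, lim)) +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "x (µm)", y = "y (µm)",
      title = sprintf("Gradient-minus-uniform traction (A = %+.3f)",
                      object$asymmetry)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.durotaxis_sweep <- function(object, ...) {
  df <- dplyr::mutate(object,
                      at = ifelse(.data$vary == "gradient",
                                  .data$gradient, .data$rbar))
  ggplot2::ggplot(df, ggplot2::aes(.data$at, .data$a_mean)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$a_mean - .data$a_se,
                                          ymax = .data$a_mean + .data$a_se)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~ .data$vary, scales = "free_x") +
    ggplot2::labs(x = "gradient (Pa/µm) / radius (µm)",
                  y = "stiff-side asymmetry A") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.tfm_error_report <- function(object, ...) {
  ggplot2::ggplot(object$per_sample, ggplot2::aes(.data$epsilon_t)) +
    ggplot2::geom_histogram(bins = 20, fill = "steelblue", colour = "white") +
    ggplot2::geom_vline(xintercept = object$epsilon_t, linetype = 2) +
    ggplot2::labs(x = expression(epsilon[T]), y = "samples",
                  title = sprintf("Mean pixelwise error %.1f%%",
                                  100 * object$epsilon_t)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.contractility_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$ebar_pred / 1000,
                                       .data$sigma_pred)) +
    ggplot2::geom_point(shape = 1, size = 2) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$sigma_pred - .data$sigma_pred_sd,
                                        ymax = .data$sigma_pred + .data$sigma_pred_sd),
                           width = 0) +
    ggplot2::geom_line(ggplot2::aes(.data$e_s / 1000, .data$sigma_true),
                       linetype = 2) +
    ggplot2::labs(x = "mean substrate stiffness (kPa)",
                  y = expression(sigma[A] ~ "(Pa)"),
                  title = "Recovered contractility-stiffness relation") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.dtfm_gan <- function(object, ...) {
  df <- tidyr::pivot_longer(object$history, -"epoch",
                            names_to = "term", values_to = "value")
  df <- df[is.finite(df$value), ]
  ggplot2::ggplot(df, ggplot2::aes(.data$epoch, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~ .data$term, scales = "free_y") +
    ggplot2::labs(x = "epoch", y = NULL, title = "Training history") +
    ggplot2::theme_minimal()
}

#' @export
tidy.dtfm_gan <- function(x, ...) x$history

#' @export
glance.dtfm_gan <- function(x, ...) {
  last <- x$history[nrow(x$history), ]
  tibble::tibble(
    epochs = nrow(x$history),
    d_loss = last$d_loss,
    g_adv = last$g_adv,
    g_rec = last$g_rec,
    n_train = length(x$split$train),
    n = x$n
  )
}

#' @export
tidy.dtfm_inverse <- function(x, ...) x$history

#' @export
glance.dtfm_inverse <- function(x, ...) {
  last <- x$history[nrow(x$history), ]
  tibble::tibble(
    epochs = nrow(x$history),
    map_mse = last$map_mse,
    sigma_mse = last$sigma_mse,
    n_train = length(x$split$train),
    n = x$n
  )
}
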