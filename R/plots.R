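# ---- ggplot2 displays ------------------------------------------------------

#' Display an image matrix with ggplot2
#'
#' Raster display with the row index increasing downward (microscopy
#' convention).
#'
#' @param img Numeric matrix.
#' @param title Optional title.
#' @return A ggplot object.
#' @export
plot_image <- function(img, title = NULL) {
  df <- tidyr::expand_grid(row = seq_len(nrow(img)),
                           col = seq_len(ncol(img)))
  df$value <- as.vector(img)
  ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = title, x = NULL, y = NULL, fill = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.lift_sinogram <- function(object, ...) {
  if (length(dim(object$rows)) != 2) {
    stop("autoplot supports static sinograms", call. = FALSE)
  }
  plot_image(object$rows, title = "sinogram (rows: view/angle plan order)") +
    ggplot2::labs(x = "detector pixel", y = "sinogram row")
}

#' @export
autoplot.lift_sweep <- function(object, ...) {
  xvar <- if ("cr" %in% names(object)) "cr" else "M"
  df <- tidyr::pivot_longer(object,
                            cols = dplyr::any_of(c("psnr_db", "ssim")),
                            names_to = "metric", values_to = "value")
  p <- ggplot2::ggplot(df, ggplot2::aes(.data[[xvar]], .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::theme_minimal() +
    ggplot2::labs(x = if (xvar == "cr") "compression ratio" else
      "peak photon budget M")
  if (xvar == "M") p <- p + ggplot2::scale_x_log10()
  p
}

#' @export
autoplot.lift_phasor_cloud <- function(object, ...) {
  ang <- seq(0, pi, length.out = 200)
  semi <- tibble::tibble(G = 0.5 + 0.5 * cos(ang), S = 0.5 * sin(ang))
  p <- ggplot2::ggplot(object, ggplot2::aes(.data$G, .data$S))
  if ("cluster" %in% names(object)) {
    p <- p + ggplot2::geom_point(
      ggplot2::aes(colour = factor(.data$cluster)), alpha = 0.6, size = 0.8) +
      ggplot2::labs(colour = "cluster")
  } else {
    p <- p + ggplot2::geom_point(alpha = 0.6, size = 0.8)
  }
  if (identical(attr(object, "domain"), "temporal")) {
    p <- p + ggplot2::geom_path(data = semi, linetype = 2, colour = "grey40")
  }
  p + ggplot2::coord_fixed() + ggplot2::theme_minimal()
}

#' @export
autoplot.lift_tau_hist <- function(object, ...) {
  peaks <- attr(object, "peaks_ns")
  p <- ggplot2::ggplot(object, ggplot2::aes(.data$tau_ns, .data$count)) +
    ggplot2::geom_col(width = diff(object$tau_ns[1:2]) * 0.9) +
    ggplot2::theme_minimal() +
    ggplot2::labs(x = "lifetime (ns)", y = "pixels")
  if (length(peaks)) {
    p <- p + ggplot2::geom_vline(xintercept = peaks, linetype = 2,
                                 colour = "red")
  }
  p
}

#' @export
autoplot.lift_depth_stack <- function(object, ...) {
  dfs <- purrr::map2_dfr(object$images, object$depths_um, function(im, d) {
    df <- tidyr::expand_grid(row = seq_len(nrow(im)), col = seq_len(ncol(im)))
    df$value <- as.vector(im)
    df$depth <- d
    df
  })
  ggplot2::ggplot(dfs, ggplot2::aes(.data$col, .data$row,
                                    fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_fixed() +
    ggplot2::facet_wrap(~depth, labeller = ggplot2::label_both) +
    ggplot2::theme_minimal() +
    ggplot2::labs(x = NULL, y = NULL, fill = NULL)
}
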