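#' Width-to-area response curve of a circular aperture
#'
#' The curvilinear relation between a centred leaf's width and its enclosed
#' area, from zero to full coverage at the internal diameter.
#'
#' @inheritParams width_area
#' @param n Number of curve points.
#' @return A ggplot.
#' @export
plot_width_area_curve <- function(gasket = gasket_preset("6400-40"), n = 200) {
  g <- as_gasket(gasket)
  w <- seq(0, 2 * g$radius_cm, length.out = n)
  df <- suppressWarnings(width_area(w, gasket = g))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$width_WL, y = .data$enclosed_area_wAL)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::geom_hline(yintercept = g$area_cm2, linetype = 2, colour = "grey50") +
    ggplot2::labs(x = expression(W[L] ~ "(cm)"),
                  y = expression(italic(w) * A[L] ~ (cm^2)),
                  title = "Enclosed leaf area vs leaf width") +
    ggplot2::theme_minimal()
}

#' Plot method-agreement results
#'
#' Scatter of width-based vs image-based areas with the fitted
#' zero-intercept line and the identity line.
#'
#' @param object An [area_agreement()] object.
#' @param ... Unused.
#' @return A ggplot.
#' @importFrom ggplot2 autoplot
#' @method autoplot area_agreement
#' @export
autoplot.area_agreement <- function(object, ...) {
  g <- glance(object)
  ggplot2::ggplot(object$per_leaf,
                  ggplot2::aes(x = .data$iAL_cm2, y = .data$wAL_cm2)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey70",
                         linetype = 2) +
    ggplot2::geom_abline(slope = g$slope, intercept = 0, colour = "steelblue") +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(
      x = expression(italic(i) * A[L] ~ (cm^2)),
      y = expression(italic(w) * A[L] ~ (cm^2)),
      title = sprintf("Y = %.3f X,  R² = %.3f,  n = %d", g$slope,
                      g$r.squared, g$n)
    ) +
    ggplot2::theme_minimal()
}

#' Plot a segmentation mask over its scene
#'
#' @param object A `leaf_mask` from [segment_leaf()].
#' @param ... Unused.
#' @return A ggplot raster of the mask.
#' @importFrom ggplot2 autoplot
#' @method autoplot leaf_mask
#' @export
autoplot.leaf_mask <- function(object, ...) {
  m <- object$mask
  df <- tidyr::expand_grid(row = seq_len(nrow(m)), col = seq_len(ncol(m)))
  df$leaf <- as.vector(m)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$leaf)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "white", `TRUE` = "darkgreen"),
                               guide = "none") +
    ggplot2::labs(title = sprintf("Leaf mask: %.3f cm²", object$area_cm2),
                  x = NULL, y = NULL) +
    ggplot2::theme_void()
}

#' Plot the uncorrected-error curve
#'
#' Percentage error in any per-area rate when the enclosed area deviates from
#' the aperture area but the instrument still assumes full coverage.
#'
#' @inheritParams width_area
#' @param from Smallest enclosed area shown, as a fraction of the aperture.
#' @return A ggplot.
#' @export
plot_uncorrected_error <- function(gasket = gasket_preset("6400-40"),
                                   from = 0.25) {
  g <- as_gasket(gasket)
  al <- seq(from * g$area_cm2, g$area_cm2, length.out = 200)
  df <- tibble::tibble(AL = al, error = uncorrected_error_percent(al, g))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$AL, y = .data$error)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::labs(x = expression(A[L] ~ (cm^2)),
                  y = "uncorrected per-area rate error (%)") +
    ggplot2::theme_minimal()
}
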