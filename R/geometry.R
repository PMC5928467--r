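#' Circle-segment geometry for a leaf strip inside a circular aperture
#'
#' A cereal leaf narrower than the gasket aperture, centred on the aperture,
#' leaves two equal empty circle segments beside its margins. Each segment is
#' part of a circle sector that splits into the segment plus an isosceles
#' triangle, so the enclosed leaf area follows from the aperture area minus
#' twice the segment area. These helpers expose the individual pieces;
#' [width_area()] assembles them.
#'
#' All angles are handled in radians internally; `central_angle()` reports
#' degrees, the convention used on instrument datasheets.
#'
#' @name circle-geometry
NULL

# Clamp an arccos argument that drifted out of [-1, 1] by rounding only.
clamp_unit <- function(z, tol = 1e-9) {
  bad <- abs(z) > 1 + tol
  if (any(bad, na.rm = TRUE)) {
    stop(sprintf(
      "invalid-width: |half width / radius| = %.6g exceeds 1 beyond rounding tolerance",
      max(abs(z[bad]))
    ), call. = FALSE)
  }
  pmin(1, pmax(-1, z))
}

check_half_width <- function(half_width, radius) {
  if (any(!is.finite(half_width)) || any(half_width < 0)) {
    stop("invalid-width: half width must be finite and >= 0", call. = FALSE)
  }
  if (any(!is.finite(radius)) || any(radius <= 0)) {
    stop("invalid-gasket: radius must be positive", call. = FALSE)
  }
  if (any(half_width / radius > 1 + 1e-9)) {
    stop("invalid-width: half width exceeds the aperture radius", call. = FALSE)
  }
  invisible(NULL)
}

#' @describeIn circle-geometry Central angle (degrees) of the sector cut off
#'   by a chord at distance `half_width` from the centre:
#'   theta = 2 * arccos(y / r) * 180 / pi. Monotone decreasing in `half_width`.
#' @param half_width Distance from aperture centre to the chord (= W_L / 2), cm.
#' @param radius Aperture radius, cm.
#' @examples
#' central_angle(0, 1)   # 180: the chord is a diameter
#' central_angle(1, 1)   # 0: the chord is tangent
#' @export
central_angle <- function(half_width, radius) {
  check_half_width(half_width, radius)
  2 * acos(clamp_unit(half_width / radius)) * 180 / pi
}

#' @describeIn circle-geometry Area of a circle sector,
#'   pi * r^2 * theta / 360, with `theta` in degrees.
#' @param theta Central angle in degrees, in \[0, 360\].
#' @export
sector_area <- function(radius, theta) {
  if (any(!is.finite(radius)) || any(radius <= 0)) {
    stop("invalid-gasket: radius must be positive", call. = FALSE)
  }
  if (any(!is.finite(theta)) || any(theta < 0) || any(theta > 360)) {
    stop("invalid-angle: theta must lie in [0, 360] degrees", call. = FALSE)
  }
  pi * radius^2 * theta / 360
}

#' @describeIn circle-geometry Area of the isosceles triangle between the
#'   chord and the two radii to its endpoints: y * sqrt(r^2 - y^2).
#' @export
isosceles_triangle_area <- function(half_width, radius) {
  check_half_width(half_width, radius)
  half_width * sqrt(pmax(0, radius^2 - half_width^2))
}

#' @describeIn circle-geometry Area of the circle segment beyond the chord:
#'   sector minus triangle. Non-negative for all valid inputs.
#' @export
segment_area <- function(half_width, radius) {
  check_half_width(half_width, radius)
  pmax(0, sector_area(radius, central_angle(half_width, radius)) -
         isosceles_triangle_area(half_width, radius))
}

#' Enclosed leaf area from a single leaf-width measurement
#'
#' Estimates the leaf area inside a circular gasket aperture from the blade
#' width at the chord through the aperture centre, assuming the midrib passes
#' through the centre and the margins run parallel across the aperture. The
#' enclosed area is the aperture area minus the two empty circle segments
#' beside the margins. A width at or beyond the internal diameter means full
#' coverage: the aperture area is returned with `clipped = TRUE` (plus a
#' warning), since that is the regime the instrument already assumes.
#'
#' `width_area()` returns the full construction as a tibble (one row per
#' width); [width_based_area()] is the scalar-convenience wrapper returning
#' only the area.
#'
#' @param width_cm Leaf blade width(s) at the aperture-centre chord. With
#'   `units = "mm"` the value is interpreted in mm and converted on entry.
#' @param gasket A [gasket_spec()] or a bare aperture area in cm^2.
#'   Default: the 2 cm^2 `"6400-40"` preset.
#' @param units Unit of `width_cm` on input; output is always cm / cm^2.
#'
#' @return A tibble with columns `width_WL`, `half_width_y`, `half_chord_x`,
#'   `central_angle_theta` (degrees), `sector_area`, `triangle_area`,
#'   `segment_area`, `enclosed_area_wAL` (all cm or cm^2) and `clipped`.
#' @examples
#' width_area(c(0.5, 1.0, 1.6))
#' width_based_area(1.0) # 1.484097 cm^2 under the 2 cm^2 aperture
#' @export
width_area <- function(width_cm, gasket = gasket_preset("6400-40"),
                       units = c("cm", "mm")) {
  units <- match.arg(units)
  g <- as_gasket(gasket)
  if (!is.numeric(width_cm) || any(!is.finite(width_cm)) || any(width_cm < 0)) {
    stop("invalid-width: leaf width must be finite and >= 0", call. = FALSE)
  }
  w <- if (units == "mm") width_cm / 10 else width_cm
  r <- g$radius_cm
  clipped <- w >= 2 * r
  if (any(clipped)) {
    warning("leaf width >= aperture diameter for ", sum(clipped),
            " value(s): full coverage assumed (clipped)", call. = FALSE)
  }
  y <- pmin(w / 2, r)
  theta <- central_angle(y, r)
  sect <- sector_area(r, theta)
  tri <- isosceles_triangle_area(y, r)
  seg <- pmax(0, sect - tri)
  tibble::tibble(
    width_WL = w,
    half_width_y = y,
    half_chord_x = sqrt(pmax(0, r^2 - y^2)),
    central_angle_theta = theta,
    sector_area = sect,
    triangle_area = tri,
    segment_area = seg,
    enclosed_area_wAL = pmin(g$area_cm2, pmax(0, g$area_cm2 - 2 * seg)),
    clipped = clipped
  )
}

#' @rdname width_area
#' @export
width_based_area <- function(width_cm, gasket = gasket_preset("6400-40"),
                             units = c("cm", "mm")) {
  width_area(width_cm, gasket = gasket, units = units)$enclosed_area_wAL
}

#' Error of neglecting the area correction
#'
#' When the instrument assumes the leaf fills the aperture but only `A_L`
#' actually does, every per-area rate is understated by the factor
#' `A_L / A_G`; the resulting percentage error in, e.g., net photosynthesis is
#' `100 * (A_G / A_L - 1)`. Zero at full coverage, growing without bound as
#' the enclosed area shrinks.
#'
#' @param measured_area_cm2 True enclosed leaf area(s) A_L, cm^2, positive.
#' @inheritParams width_area
#' @return Percentage error(s), same length as `measured_area_cm2`.
#' @examples
#' uncorrected_error_percent(1) # +100% with the 2 cm^2 aperture
#' @export
uncorrected_error_percent <- function(measured_area_cm2,
                                      gasket = gasket_preset("6400-40")) {
  g <- as_gasket(gasket)
  if (!is.numeric(measured_area_cm2) || any(!is.finite(measured_area_cm2)) ||
      any(measured_area_cm2 <= 0)) {
    stop("invalid-area: measured area must be positive", call. = FALSE)
  }
  100 * (g$area_cm2 / measured_area_cm2 - 1)
}

#' Tabulate an area estimate
#'
#' Normalises an area value from any of the estimators into the one-row
#' tibble used across the package.
#'
#' @param value Area in cm^2.
#' @param method One of `"width_based"`, `"image_based"`, `"oracle"`.
#' @inheritParams width_area
#' @return A tibble with `area_cm2`, `method`, `gasket_area_cm2`.
#' @export
area_estimate <- function(value, method = c("width_based", "image_based", "oracle"),
                          gasket = gasket_preset("6400-40")) {
  method <- match.arg(method)
  g <- as_gasket(gasket)
  if (any(!is.finite(value)) || any(value < 0)) {
    stop("invalid-area: area estimate must be finite and >= 0", call. = FALSE)
  }
  tibble::tibble(area_cm2 = value, method = method, gasket_area_cm2 = g$area_cm2)
}
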