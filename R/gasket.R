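#' Describe a circular gas-exchange chamber gasket
#'
#' A gasket spec carries the internal aperture area of a clamp-on leaf
#' chamber and the internal radius derived from it. The aperture area is the
#' leaf area the instrument assumes when it reports per-area rates, so every
#' area estimator in this package is expressed relative to it.
#'
#' @param area_cm2 Internal aperture area in cm^2. Must be positive.
#' @param shape Aperture shape. Only `"circular"` is supported.
#' @param name Optional label (e.g. a chamber model) carried in printing.
#'
#' @return An object of class `gasket_spec`: a list with `shape`, `area_cm2`,
#'   `radius_cm` and `name`.
#' @seealso [gasket_preset()] for built-in chambers, [radius_from_area()].
#' @examples
#' gasket_spec(2)
#' gasket_spec(2)$radius_cm # sqrt(2 / pi)
#' @export
gasket_spec <- function(area_cm2, shape = "circular", name = NULL) {
  shape <- match.arg(shape, "circular")
  if (!is.numeric(area_cm2) || length(area_cm2) != 1L || !is.finite(area_cm2)) {
    stop("invalid-gasket: `area_cm2` must be a single finite number", call. = FALSE)
  }
  structure(
    list(
      shape = shape,
      area_cm2 = as.numeric(area_cm2),
      radius_cm = radius_from_area(area_cm2),
      name = name
    ),
    class = "gasket_spec"
  )
}

#' Built-in gasket presets
#'
#' `"6400-40"` is the circular leaf chamber fluorometer aperture with an
#' internal area of 2 cm^2, the default throughout this package.
#'
#' @param name Preset name.
#' @return A [gasket_spec()].
#' @examples
#' gasket_preset("6400-40")
#' @export
gasket_preset <- function(name = "6400-40") {
  name <- match.arg(name, "6400-40")
  gasket_spec(2, name = name)
}

#' Internal radius of a circular aperture from its area
#'
#' Inverts the disc area relation: r = sqrt(A_G / pi).
#'
#' @param area_cm2 Aperture area(s) in cm^2, all positive.
#' @return Radius in cm, same length as `area_cm2`.
#' @examples
#' radius_from_area(pi) # 1
#' @export
radius_from_area <- function(area_cm2) {
  if (!is.numeric(area_cm2) || length(area_cm2) == 0L ||
      any(!is.finite(area_cm2)) || any(area_cm2 <= 0)) {
    stop("invalid-gasket: aperture area must be positive and finite", call. = FALSE)
  }
  sqrt(area_cm2 / pi)
}

# Accept a gasket_spec or a bare numeric area.
as_gasket <- function(gasket) {
  if (inherits(gasket, "gasket_spec")) return(gasket)
  if (is.numeric(gasket) && length(gasket) == 1L) return(gasket_spec(gasket))
  stop("invalid-gasket: pass a gasket_spec() or a single area in cm^2", call. = FALSE)
}

#' @export
print.gasket_spec <- function(x, ...) {
  nm <- if (is.null(x$name)) "" else paste0(" [", x$name, "]")
  cat(sprintf(
    "<gasket_spec>%s circular aperture: area %.4f cm^2, radius %.4f cm\n",
    nm, x$area_cm2, x$radius_cm
  ))
  invisible(x)
}
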