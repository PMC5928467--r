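#' Load a raster image as a grayscale matrix
#'
#' Reads PNG/TIFF/JPEG via EBImage and returns a base matrix in row/column
#' (top-left origin) orientation with intensities in \[0, 1\]. RGB images are
#' reduced to luminance (0.2126 R + 0.7152 G + 0.0722 B) by default; the
#' `"green"` channel is available because leaves are green-dominant.
#'
#' @param image A file path, a numeric matrix (grayscale), or a
#'   rows x cols x channels array.
#' @param channel `"luminance"` or `"green"` for colour input.
#' @return A numeric matrix, rows = image rows.
#' @export
load_image <- function(image, channel = c("luminance", "green")) {
  channel <- match.arg(channel)
  if (is.character(image)) {
    if (!file.exists(image)) {
      stop("read error: file not found: ", image, call. = FALSE)
    }
    img <- tryCatch(EBImage::readImage(image),
                    error = function(e) stop("read error: ", conditionMessage(e),
                                             call. = FALSE))
    d <- dim(img)
    if (length(d) == 2L) {
      return(t(EBImage::imageData(img)))  # EBImage stores (x, y)
    }
    dat <- EBImage::imageData(img)
    arr <- aperm(dat[, , 1:3, drop = FALSE], c(2, 1, 3))
    image <- arr
  }
  if (is.matrix(image)) return(image)
  if (is.array(image) && length(dim(image)) == 3L) {
    if (channel == "green") return(image[, , 2])
    return(0.2126 * image[, , 1] + 0.7152 * image[, , 2] + 0.0722 * image[, , 3])
  }
  stop("read error: unsupported image input", call. = FALSE)
}

# Bounding boxes, sizes and border contact for each connected component.
component_stats <- function(mask) {
  lab <- EBImage::bwlabel(mask)
  n <- max(lab)
  if (n == 0) return(NULL)
  idx <- which(lab > 0)
  rr <- (idx - 1L) %% nrow(mask) + 1L
  cc <- (idx - 1L) %/% nrow(mask) + 1L
  lb <- lab[idx]
  tibble::tibble(
    label = seq_len(n),
    size = tabulate(lb, n),
    r0 = tapply(rr, lb, min), r1 = tapply(rr, lb, max),
    c0 = tapply(cc, lb, min), c1 = tapply(cc, lb, max)
  ) |>
    dplyr::mutate(
      height = .data$r1 - .data$r0 + 1L,
      width = .data$c1 - .data$c0 + 1L,
      aspect = pmax(.data$height, .data$width) / pmin(.data$height, .data$width),
      touches_border = .data$r0 == 1L | .data$c0 == 1L |
        .data$r1 == nrow(mask) | .data$c1 == ncol(mask)
    )
}

#' Calibrate the pixel scale from a printed scale bar
#'
#' Finds the printed bar as the largest dark connected component with an
#' aspect ratio of at least 5 that does not touch the image border (the blade
#' itself typically runs off-frame), and measures its extent along its major
#' axis. The pixel scale is that extent divided by the known bar length.
#'
#' @inheritParams load_image
#' @param bar_length_cm Printed bar length; 1 cm in the standard layout.
#' @param bar_roi Optional pixel rectangle `c(row0, row1, col0, col1)`
#'   restricting the search (border exclusion is then lifted).
#' @return Pixel scale in px/cm.
#' @export
calibrate_scale <- function(image, bar_length_cm = 1, bar_roi = NULL,
                            channel = c("luminance", "green")) {
  img <- load_image(image, channel)
  cropped <- !is.null(bar_roi)
  if (cropped) {
    stopifnot(length(bar_roi) == 4L)
    img <- img[bar_roi[1]:bar_roi[2], bar_roi[3]:bar_roi[4], drop = FALSE]
  }
  dark <- img < otsu_threshold(img)
  stats <- component_stats(dark)
  cand <- if (is.null(stats)) NULL else
    dplyr::filter(stats, .data$aspect >= 5, cropped | !.data$touches_border)
  if (is.null(cand) || nrow(cand) == 0) {
    stop("scale-not-found: no dark bar-like component (aspect >= 5) detected; ",
         "pass px_per_cm directly or supply bar_roi", call. = FALSE)
  }
  best <- cand[which.max(cand$size), ]
  max(best$height, best$width) / bar_length_cm
}

# Otsu threshold of a vector/matrix of intensities in [0, 1].
otsu_threshold <- function(x) {
  v <- as.numeric(x)
  if (diff(range(v)) < 1e-6) return(min(v) - 1e-9)  # flat image: nothing dark
  EBImage::otsu(EBImage::Image(matrix(v, ncol = 1)), range = c(0, 1))
}

# Linear FFT cross-correlation of an image with a centred kernel; returns a
# matrix of the same size as `a` giving, for each pixel taken as the kernel
# centre, the kernel-weighted sum over `a`.
ring_correlate <- function(a, k) {
  kc <- (dim(k) + 1) / 2
  d <- dim(a) + dim(k)
  d2 <- c(stats::nextn(d[1], 2), stats::nextn(d[2], 2))
  pa <- matrix(0, d2[1], d2[2]); pa[seq_len(nrow(a)), seq_len(ncol(a))] <- a
  pk <- matrix(0, d2[1], d2[2]); pk[seq_len(nrow(k)), seq_len(ncol(k))] <- k
  conv <- Re(stats::fft(stats::fft(pa) * Conj(stats::fft(pk)), inverse = TRUE)) /
    prod(d2)
  # cross-correlation: result index i corresponds to centre i + kc - 1 in `a`
  rows <- seq_len(nrow(a)); cols <- seq_len(ncol(a))
  shift <- function(i, n, size) ((i + size - 1L) %% size) + 1L
  conv[shift(rows - kc[1] + 1L, nrow(a), d2[1]),
       shift(cols - kc[2] + 1L, ncol(a), d2[2])]
}

ring_kernel <- function(radius, width = 0.75) {
  n <- 2 * ceiling(radius + width) + 1
  ctr <- (n + 1) / 2
  d <- sqrt(outer((seq_len(n) - ctr)^2, (seq_len(n) - ctr)^2, `+`))
  (abs(d - radius) <= width) * 1
}

#' Locate the printed gasket-impression circle
#'
#' A Hough-style circular accumulator: edge pixels of the dark regions vote,
#' via FFT ring correlation, for every candidate centre at each candidate
#' radius; the global vote maximum gives the circle. The peak must be
#' supported by at least half the circumference, otherwise a
#' `circle-not-found` error asks for a manual `--circle` override. The radius
#' is refined to sub-pixel precision as the mean distance of supporting edge
#' pixels from the recovered centre.
#'
#' @inheritParams load_image
#' @param expected_radius_px Optional radius prior; the search is restricted
#'   to +/-15% of it.
#' @param min_support Minimum fraction of the circumference that must vote.
#' @return A named vector `c(center_row, center_col, radius_px)`.
#' @export
locate_gasket_circle <- function(image, expected_radius_px = NULL,
                                 min_support = 0.5,
                                 channel = c("luminance", "green")) {
  img <- load_image(image, channel)
  # two-level thresholding: dark1 = everything darker than background
  # (leaf, printed outline, bar); dark2 = the darkest class only (printed
  # ink), which keeps the outline's inner edge visible even when the leaf
  # covers the whole aperture
  dark1 <- img < otsu_threshold(img)
  dark2 <- dark1
  if (any(dark1)) {
    thr2 <- otsu_threshold(img[dark1])
    if (mean(img[dark1] < thr2) > 0.001) dark2 <- img < thr2
  }
  boundary <- function(m) {
    m & !(EBImage::erode(m * 1, EBImage::makeBrush(3, "box")) > 0.5)
  }
  edges2 <- boundary(dark2)  # printed-ink edges only
  edges <- boundary(dark1) | edges2
  e <- edges * 1

  search <- function(radii) {
    best <- list(score = -Inf)
    for (R in radii) {
      acc <- ring_correlate(e, ring_kernel(R))
      i <- arrayInd(which.max(acc), dim(acc))
      score <- max(acc) / (2 * pi * R)
      if (score > best$score) {
        best <- list(score = score, row = i[1], col = i[2], R = R)
      }
    }
    best
  }

  if (!is.null(expected_radius_px)) {
    radii <- seq(0.85 * expected_radius_px, 1.15 * expected_radius_px,
                 by = max(1, round(0.02 * expected_radius_px)))
    best <- search(radii)
  } else {
    m <- min(dim(img))
    best <- search(round(seq(0.12 * m, 0.48 * m, length.out = 14)))
    best <- search(seq(max(3, round(best$R * 0.92)), round(best$R * 1.08), by = 1))
  }
  if (best$score < min_support) {
    stop("circle-not-found: no circular outline with sufficient support ",
         sprintf("(best %.2f < %.2f)", best$score, min_support),
         "; supply the circle manually (e.g. --circle ROW,COL,R_PX)",
         call. = FALSE)
  }
  # sub-pixel radius: the aperture is the *inner* edge of the printed
  # outline. Refine on the printed-ink edges when they support the ring
  # (they exclude leaf margins); otherwise fall back to all edges. The lower
  # half of the supporting distances isolates the inner outline edge.
  ring_distances <- function(mask) {
    idx <- which(mask)
    rr <- (idx - 1L) %% nrow(img) + 1L
    cc <- (idx - 1L) %/% nrow(img) + 1L
    d <- sqrt((rr - best$row)^2 + (cc - best$col)^2)
    d[abs(d - best$R) <= 2.5]
  }
  keep <- ring_distances(edges2)
  if (length(keep) < pi * best$R) keep <- ring_distances(edges)
  # inner-edge pixel centres sit on average half a pixel inside the
  # continuous ink boundary; subtract that quantization offset
  radius <- if (length(keep)) {
    mean(keep[keep <= stats::median(keep)]) - 0.5
  } else best$R
  c(center_row = as.numeric(best$row), center_col = as.numeric(best$col),
    radius_px = radius)
}

#' Assemble a calibrated leaf-image scene
#'
#' Bundles the grayscale image, the pixel scale and the aperture circle (in
#' pixel coordinates) into the object [segment_leaf()] consumes. When a
#' gasket spec is attached the detected circle must agree with the declared
#' aperture area within 2%, and the aperture disc used for area accounting is
#' re-derived from the declared area (the printed impression line sits just
#' outside the true aperture).
#'
#' @inheritParams load_image
#' @param px_per_cm Pixel scale, px/cm, > 0.
#' @param circle Named or positional vector `(center_row, center_col,
#'   radius_px)`.
#' @param gasket Optional [gasket_spec()] (or area in cm^2) to validate and
#'   anchor the aperture radius.
#' @param provenance How the circle was obtained.
#' @return An object of class `leaf_scene`.
#' @export
leaf_image_scene <- function(image, px_per_cm, circle, gasket = NULL,
                             provenance = c("detected", "user_supplied"),
                             channel = c("luminance", "green")) {
  img <- load_image(image, channel)
  provenance <- match.arg(provenance)
  if (!is.numeric(px_per_cm) || px_per_cm <= 0) {
    stop("invalid-scale: px_per_cm must be positive", call. = FALSE)
  }
  if (px_per_cm < 50) {
    warning("resolution below the supported minimum of 50 px/cm; ",
            "area quantization may be coarse", call. = FALSE)
  }
  circle <- as.numeric(circle)
  stopifnot(length(circle) == 3L)
  if (circle[1] - circle[3] < 0 || circle[2] - circle[3] < 0 ||
      circle[1] + circle[3] > nrow(img) || circle[2] + circle[3] > ncol(img)) {
    stop("invalid-circle: aperture circle extends beyond the image", call. = FALSE)
  }
  aperture_radius_px <- circle[3]
  if (!is.null(gasket)) {
    g <- as_gasket(gasket)
    implied <- pi * (circle[3] / px_per_cm)^2
    if (abs(implied / g$area_cm2 - 1) > 0.02) {
      stop(sprintf(
        "invalid-circle: detected circle implies %.3f cm^2, declared aperture is %.3f cm^2 (>2%% off)",
        implied, g$area_cm2), call. = FALSE)
    }
    aperture_radius_px <- g$radius_cm * px_per_cm
    gasket <- g
  }
  structure(
    list(image = img, px_per_cm = px_per_cm,
         circle = c(center_row = circle[1], center_col = circle[2],
                    radius_px = circle[3]),
         aperture_radius_px = aperture_radius_px,
         gasket = gasket, provenance = provenance),
    class = "leaf_scene"
  )
}

#' Segment the leaf inside the aperture disc
#'
#' Automates the freehand tracing step of the manual procedure: an Otsu
#' threshold is computed on pixels strictly inside the aperture (excluding a
#' rim band that drops the printed outline), below-threshold pixels are kept,
#' a morphological closing (disc brush) heals small gaps, the largest
#' connected component is selected, and the mask is intersected with the
#' aperture disc. Pixel-centre membership defines the disc; area is the pixel
#' count divided by the squared scale.
#'
#' Degenerate contrast inside the disc falls back to the out-of-disc
#' reference: an essentially uniform dark disc is full coverage (the mask is
#' the whole disc); a uniform bright disc with Otsu claiming near-total
#' foreground raises an `ambiguous-contrast` error. Foreground below 0.5% of
#' the disc yields area 0 with an `empty-leaf` warning.
#'
#' @param scene A [leaf_image_scene()].
#' @param rim_band_px Width of the rim exclusion band for thresholding, px.
#' @return An object of class `leaf_mask`: `mask` (logical matrix),
#'   `pixel_count`, `area_cm2`, `threshold`, `px_per_cm`.
#' @export
segment_leaf <- function(scene, rim_band_px = 2) {
  stopifnot(inherits(scene, "leaf_scene"))
  img <- scene$image
  ctr <- scene$circle
  R <- scene$aperture_radius_px
  dist <- sqrt(outer((seq_len(nrow(img)) - ctr[1])^2,
                     (seq_len(ncol(img)) - ctr[2])^2, `+`))
  disc <- dist <= R
  inner <- dist <= R - rim_band_px
  vals <- img[inner]
  thr <- otsu_threshold(vals)
  fg_frac <- mean(vals < thr)
  # Otsu between-class separation; tiny separation means the aperture is
  # essentially uniform (all leaf, or all background) and the threshold is
  # splitting texture, not leaf from paper
  separation <- if (fg_frac > 0 && fg_frac < 1) {
    mean(vals[vals >= thr]) - mean(vals[vals < thr])
  } else 0

  if (separation < 0.15) {
    if (mean(vals) < 0.5) {
      return(new_leaf_mask(disc, scene, thr))  # uniformly dark: full coverage
    }
    if (fg_frac > 0.995) {
      stop("ambiguous-contrast: near-total foreground on a bright aperture; ",
           "check illumination/contrast", call. = FALSE)
    }
    warning("empty-leaf: no foreground found inside the aperture; area is 0",
            call. = FALSE)
    return(new_leaf_mask(disc & FALSE, scene, thr))
  }
  if (fg_frac > 0.995) return(new_leaf_mask(disc, scene, thr))
  if (fg_frac < 0.005) {
    warning("empty-leaf: foreground below 0.5% of the aperture; area is 0",
            call. = FALSE)
    return(new_leaf_mask(disc & FALSE, scene, thr))
  }

  mask <- (img < thr) & disc
  mask <- EBImage::closing(mask * 1, EBImage::makeBrush(5, "disc")) > 0.5
  lab <- EBImage::bwlabel(mask)
  if (max(lab) > 0) {
    sizes <- tabulate(lab[lab > 0], max(lab))
    mask <- lab == which.max(sizes)
  }
  mask <- mask & disc
  if (sum(mask) < 0.005 * sum(disc)) {
    warning("empty-leaf: foreground below 0.5% of the aperture; area is ~0",
            call. = FALSE)
  }
  new_leaf_mask(mask, scene, thr)
}

new_leaf_mask <- function(mask, scene, threshold) {
  structure(
    list(mask = mask, pixel_count = sum(mask),
         area_cm2 = sum(mask) / scene$px_per_cm^2,
         threshold = threshold, px_per_cm = scene$px_per_cm),
    class = "leaf_mask"
  )
}

#' @export
print.leaf_mask <- function(x, ...) {
  cat(sprintf("<leaf_mask> %d px, %.4f cm^2 at %.1f px/cm (threshold %.3f)\n",
              x$pixel_count, x$area_cm2, x$px_per_cm, x$threshold))
  invisible(x)
}

#' Image-based enclosed leaf area
#'
#' End-to-end pipeline for a photograph of a leaf under a printed gasket
#' impression: calibrate the pixel scale from the 1 cm bar, locate the
#' impression circle, segment the leaf inside the aperture, and report the
#' enclosed area. Every stage can be overridden (`px_per_cm`, `circle`) when
#' automatic detection is unsuitable.
#'
#' @inheritParams load_image
#' @inheritParams calibrate_scale
#' @param gasket A [gasket_spec()] or aperture area in cm^2; anchors the
#'   aperture radius and validates the detected circle.
#' @param px_per_cm Optional pixel-scale override (skips bar detection).
#' @param circle Optional `(center_row, center_col, radius_px)` override
#'   (skips circle detection).
#' @param rim_band_px Passed to [segment_leaf()].
#' @return A one-row tibble: `area_cm2`, `method = "image_based"`,
#'   `gasket_area_cm2`, `px_per_cm`, `center_row`, `center_col`, `radius_px`,
#'   `threshold`, `pixel_count`, `provenance`. The full `leaf_scene` and
#'   `leaf_mask` are attached as attributes `scene` and `mask` for audit.
#' @examples
#' leaf <- synth_leaf("constant", base_width_cm = 1)
#' sc <- render_scene(leaf, px_per_cm = 60)
#' image_based_area(sc$image)
#' @export
image_based_area <- function(image, gasket = gasket_preset("6400-40"),
                             px_per_cm = NULL, circle = NULL,
                             bar_length_cm = 1, bar_roi = NULL,
                             channel = c("luminance", "green"),
                             rim_band_px = 2) {
  img <- load_image(image, channel)
  g <- as_gasket(gasket)
  if (is.null(px_per_cm)) {
    px_per_cm <- calibrate_scale(img, bar_length_cm = bar_length_cm,
                                 bar_roi = bar_roi)
  }
  provenance <- "user_supplied"
  if (is.null(circle)) {
    circle <- locate_gasket_circle(img,
                                   expected_radius_px = g$radius_cm * px_per_cm)
    provenance <- "detected"
  }
  scene <- leaf_image_scene(img, px_per_cm = px_per_cm, circle = circle,
                            gasket = g, provenance = provenance)
  mask <- segment_leaf(scene, rim_band_px = rim_band_px)
  out <- tibble::tibble(
    area_cm2 = mask$area_cm2,
    method = "image_based",
    gasket_area_cm2 = g$area_cm2,
    px_per_cm = px_per_cm,
    center_row = scene$circle[["center_row"]],
    center_col = scene$circle[["center_col"]],
    radius_px = scene$circle[["radius_px"]],
    threshold = mask$threshold,
    pixel_count = mask$pixel_count,
    provenance = provenance
  )
  attr(out, "scene") <- scene
  attr(out, "mask") <- mask
  out
}
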