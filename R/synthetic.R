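#' Parametric synthetic cereal leaf blades
#'
#' Generates a blade width profile W(s) along the leaf, s in cm from the
#' blade base. Three families cover the grass-blade shape classes:
#' `"constant"` (parallel margins, the exact regime of the width formula),
#' `"linear"` (straight tapering margins) and `"lanceolate"` (quadratic
#' margin curvature, so the margins are neither straight nor parallel — the
#' regime where the width formula is only approximately right). Outside
#' \[0, length_cm\] the width is zero.
#'
#' With a `seed`, base width and taper are jittered by ~10% (log-normal) so a
#' population of distinct but reproducible leaves can be drawn; the same seed
#' always yields the same leaf.
#'
#' @param family Shape family.
#' @param base_width_cm Blade width at the base, cm; must be in (0, 2].
#' @param taper Dimensionless taper: the fraction of base width lost at the
#'   tip (linear: linearly in s; lanceolate: quadratically). Must be >= 0.
#' @param length_cm Blade length, cm.
#' @param seed Optional integer; jitters parameters reproducibly.
#'
#' @return An object of class `synth_leaf` with fields `family`,
#'   `base_width_cm`, `taper`, `length_cm`, `seed`.
#' @examples
#' leaf <- synth_leaf("lanceolate", base_width_cm = 0.6, length_cm = 20)
#' leaf_width_at(leaf, c(0, 10, 20))
#' @export
synth_leaf <- function(family = c("lanceolate", "linear", "constant"),
                       base_width_cm = 0.6, taper = 1, length_cm = 20,
                       seed = NULL) {
  family <- match.arg(family)
  if (!is.numeric(base_width_cm) || length(base_width_cm) != 1L ||
      !is.finite(base_width_cm) || base_width_cm <= 0 || base_width_cm > 2) {
    stop("parameter error: base_width_cm must be in (0, 2]", call. = FALSE)
  }
  if (!is.numeric(taper) || length(taper) != 1L || !is.finite(taper) || taper < 0) {
    stop("parameter error: taper must be >= 0", call. = FALSE)
  }
  if (!is.numeric(length_cm) || length(length_cm) != 1L ||
      !is.finite(length_cm) || length_cm <= 0) {
    stop("parameter error: length_cm must be positive", call. = FALSE)
  }
  if (!is.null(seed)) {
    jit <- with_local_seed(seed, stats::rlnorm(2, 0, 0.1))
    base_width_cm <- min(2, base_width_cm * jit[1])
    taper <- taper * jit[2]
  }
  structure(
    list(family = family, base_width_cm = base_width_cm, taper = taper,
         length_cm = length_cm, seed = seed),
    class = "synth_leaf"
  )
}

#' @export
print.synth_leaf <- function(x, ...) {
  cat(sprintf("<synth_leaf> %s blade: base %.3f cm, taper %.3f, length %.1f cm\n",
              x$family, x$base_width_cm, x$taper, x$length_cm))
  invisible(x)
}

#' Blade width at positions along a synthetic leaf
#'
#' @param leaf A [synth_leaf()].
#' @param s Position(s) along the blade, cm from the base.
#' @return Width(s) in cm; zero outside the blade.
#' @export
leaf_width_at <- function(leaf, s) {
  stopifnot(inherits(leaf, "synth_leaf"))
  u <- s / leaf$length_cm
  w <- switch(leaf$family,
    constant = rep(leaf$base_width_cm, length(s)),
    linear = leaf$base_width_cm * (1 - leaf$taper * u),
    lanceolate = leaf$base_width_cm * (1 - leaf$taper * u^2)
  )
  w <- pmax(0, w)
  w[s < 0 | s > leaf$length_cm] <- 0
  w
}

#' Preset blade archetypes
#'
#' Four synthetic parameter presets spanning the width range of common
#' cereal blades: wide maize-like, intermediate barley-like, and two narrow
#' wheat-like shapes. These are declared synthetic archetypes chosen for
#' realistic width ordering, not calibrated species measurements.
#'
#' @return A tibble with `archetype`, `family`, `base_width_cm`, `taper`,
#'   `length_cm`.
#' @examples
#' leaf_presets()
#' @export
leaf_presets <- function() {
  tibble::tribble(
    ~archetype,   ~family,      ~base_width_cm, ~taper, ~length_cm,
    "maize",      "lanceolate", 1.40,           1,      60,
    "barley",     "lanceolate", 0.70,           1,      25,
    "hard_wheat", "lanceolate", 0.50,           1,      20,
    "soft_wheat", "linear",     0.40,           0.8,    18
  )
}

#' Ground-truth enclosed area by numerical integration
#'
#' The independent oracle for both estimators: integrates the overlap of the
#' blade (width profile W, midrib through the aperture centre, margins
#' symmetric about the midrib) with the aperture disc of radius r. With the
#' substitution s' = centre + r sin(phi) the integrand
#' 2 * min(W(s')/2, r cos(phi)) * r cos(phi) is smooth apart from one kink,
#' so composite Simpson on >= `n_panels` panels converges fast; the result is
#' checked against a half-resolution pass (Richardson-style error estimate).
#'
#' @param leaf A [synth_leaf()].
#' @param gasket A [gasket_spec()] or aperture area in cm^2.
#' @param center_s Blade position (cm from base) at the aperture centre.
#' @param n_panels Number of integration panels (even; >= 10^4 by default).
#' @return A one-row tibble: `true_enclosed_area_cm2`, `mid_chord_width_cm`
#'   (the width a caliper at the aperture centre would read),
#'   `integration_error_cm2` (estimated absolute error).
#' @examples
#' leaf <- synth_leaf("constant", base_width_cm = 1)
#' true_enclosed_area(leaf, center_s = 10) # matches width_based_area(1)
#' @export
true_enclosed_area <- function(leaf, gasket = gasket_preset("6400-40"),
                               center_s = leaf$length_cm / 2,
                               n_panels = 1e4) {
  stopifnot(inherits(leaf, "synth_leaf"))
  g <- as_gasket(gasket)
  r <- g$radius_cm
  integrand <- function(phi) {
    chord <- r * cos(phi)  # half-extent of the disc at blade position s'
    w <- leaf_width_at(leaf, center_s + r * sin(phi))
    2 * pmin(w / 2, chord) * r * cos(phi)  # strip height x ds/dphi
  }
  area_fine <- simpson(integrand, -pi / 2, pi / 2, n_panels)
  area_coarse <- simpson(integrand, -pi / 2, pi / 2, n_panels / 2)
  tibble::tibble(
    true_enclosed_area_cm2 = min(area_fine, g$area_cm2),
    mid_chord_width_cm = leaf_width_at(leaf, center_s),
    integration_error_cm2 = abs(area_fine - area_coarse) / 15
  )
}

# Composite Simpson on n panels (rounded up to even).
simpson <- function(f, a, b, n) {
  n <- 2 * ceiling(n / 2)
  x <- seq(a, b, length.out = n + 1)
  y <- f(x)
  h <- (b - a) / n
  h / 3 * (y[1] + y[n + 1] + 4 * sum(y[seq(2, n, 2)]) + 2 * sum(y[seq(3, n - 1, 2)]))
}

#' Render a gasket-impression scene for a synthetic leaf
#'
#' Emulates the photograph taken for the image-based technique: a white
#' background, the dark blade polygon from the width profile (optionally with
#' a 10%-darker midrib stripe), a 2 px dark circular outline marking the
#' printed aperture impression (drawn outward from the true aperture radius
#' so the aperture interior stays clean), and a dark 1 cm scale bar outside
#' the circle. Additive Gaussian pixel noise is applied last, clamped to
#' \[0, 1\], deterministic per seed.
#'
#' @inheritParams true_enclosed_area
#' @param px_per_cm Rendering resolution; at least 50.
#' @param noise_sd Gaussian noise standard deviation on the \[0, 1\] scale.
#' @param seed Integer seed for the noise.
#' @param midrib_shade Render the midrib stripe 10% darker than the lamina.
#' @return An object of class `leaf_scene_render`: list with `image` (matrix,
#'   rows = image rows, values in \[0, 1\]), `px_per_cm`, `circle`
#'   (`center_row`, `center_col`, `radius_px` of the true aperture), `bar`
#'   (pixel bounding box of the scale bar), `gasket`, and `ground_truth`
#'   (tibble from [true_enclosed_area()]).
#' @examples
#' sc <- render_scene(synth_leaf("constant", base_width_cm = 1), px_per_cm = 60)
#' dim(sc$image)
#' @export
render_scene <- function(leaf, gasket = gasket_preset("6400-40"),
                         center_s = leaf$length_cm / 2, px_per_cm = 100,
                         noise_sd = 0, seed = NULL, midrib_shade = TRUE) {
  stopifnot(inherits(leaf, "synth_leaf"))
  g <- as_gasket(gasket)
  if (!is.numeric(px_per_cm) || px_per_cm < 50) {
    stop("resolution error: px_per_cm must be at least 50", call. = FALSE)
  }
  r <- g$radius_cm

  # fixed layout (cm): bar top-left, circle right-of-centre so wide blades
  # never reach the bar
  width_cm <- 5; height_cm <- 4.4
  cx <- 2.9; cy <- 2.4
  bar <- c(x0 = 0.2, x1 = 1.2, y0 = 0.15, y1 = 0.27)

  nr <- round(height_cm * px_per_cm)
  nc <- round(width_cm * px_per_cm)
  xc <- (seq_len(nc) - 0.5) / px_per_cm  # pixel-centre coordinates
  yc <- (seq_len(nr) - 0.5) / px_per_cm

  # leaf half-width per row; rows map to blade position s = center_s + (y - cy)
  s_row <- center_s + (yc - cy)
  halfw <- leaf_width_at(leaf, s_row) / 2

  # layout checks: blade and circle must stay clear of the scale bar
  bar_rows <- yc >= bar["y0"] & yc <= bar["y1"]
  if (any(halfw[bar_rows] > 0 & cx - halfw[bar_rows] < bar["x1"] + 0.2)) {
    stop("layout error: blade overlaps the scale bar region", call. = FALSE)
  }
  if (cy - r - 2 / px_per_cm < bar["y1"] + 0.2) {
    stop("layout error: aperture outline overlaps the scale bar region", call. = FALSE)
  }

  img <- matrix(1, nr, nc)
  dx <- abs(matrix(xc, nr, nc, byrow = TRUE) - cx)
  lamina <- dx <= matrix(halfw, nr, nc)
  img[lamina] <- 0.25
  if (midrib_shade) {
    midrib <- lamina & dx <= matrix(0.05 * 2 * halfw, nr, nc)
    img[midrib] <- 0.225
  }

  # printed impression: 2 px outline outward from the true aperture radius
  dy <- abs(matrix(yc, nr, nc) - cy)
  dist <- sqrt(dx^2 + dy^2)
  img[dist >= r & dist < r + 2 / px_per_cm] <- 0.05

  # 1 cm scale bar
  in_bar <- matrix(xc >= bar["x0"] & xc <= bar["x1"], nr, nc, byrow = TRUE) &
    matrix(yc >= bar["y0"] & yc <= bar["y1"], nr, nc)
  img[in_bar] <- 0.05

  if (noise_sd > 0) {
    noise <- if (is.null(seed)) stats::rnorm(nr * nc, 0, noise_sd) else
      with_local_seed(seed, stats::rnorm(nr * nc, 0, noise_sd))
    img[] <- pmin(1, pmax(0, img + noise))
  }

  structure(
    list(
      image = img,
      px_per_cm = px_per_cm,
      circle = c(center_row = cy * px_per_cm, center_col = cx * px_per_cm,
                 radius_px = r * px_per_cm),
      bar = bar * px_per_cm,
      gasket = g,
      ground_truth = true_enclosed_area(leaf, g, center_s)
    ),
    class = "leaf_scene_render"
  )
}

#' Write a rendered scene as an 8-bit grayscale PNG
#'
#' @param scene A [render_scene()] result.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_scene <- function(scene, path) {
  stopifnot(inherits(scene, "leaf_scene_render"))
  png::writePNG(scene$image, path)
  invisible(path)
}

#' Generate an internally consistent synthetic instrument log
#'
#' Draws plausible per-area gas exchange records the way a portable
#' photosynthesis system would report them under moderate light: net
#' photosynthesis 2–25 umol m^-2 s^-1, stomatal conductance 0.05–0.5
#' mol m^-2 s^-1, transpiration, intercellular CO2 and PSII operating
#' efficiency in realistic ranges, all uniform and deterministic per seed.
#' The instrument `Area` column is the gasket aperture area — the assumption
#' the correction later replaces.
#'
#' @param n_rows Number of records (>= 1).
#' @param gasket A [gasket_spec()] or aperture area in cm^2.
#' @param seed Integer seed.
#' @param al_cm2 Optional true enclosed areas, one per row; returned as a
#'   label-keyed annotation tibble alongside the log.
#' @return A list of class `synth_gas_log`: `log` (tibble with columns `Obs`,
#'   `HHMMSS`, `Area`, `Photo`, `Cond`, `Trmmol`, `Ci`, `PhiPS2`) and
#'   `areas` (tibble `label`, `AL_cm2`, or `NULL`).
#' @examples
#' synth_gas_log(3, seed = 1)$log
#' @export
synth_gas_log <- function(n_rows, gasket = gasket_preset("6400-40"),
                          seed = 1, al_cm2 = NULL) {
  if (!is.numeric(n_rows) || n_rows < 1) {
    stop("parameter error: n_rows must be >= 1", call. = FALSE)
  }
  n_rows <- as.integer(n_rows)
  g <- as_gasket(gasket)
  if (!is.null(al_cm2) && length(al_cm2) != n_rows) {
    stop("parameter error: al_cm2 must have one value per row", call. = FALSE)
  }
  draws <- with_local_seed(seed, {
    tibble::tibble(
      Photo = stats::runif(n_rows, 2, 25),
      Cond = stats::runif(n_rows, 0.05, 0.5),
      Trmmol = stats::runif(n_rows, 0.5, 5),
      Ci = stats::runif(n_rows, 200, 350),
      PhiPS2 = stats::runif(n_rows, 0.4, 0.8)
    )
  })
  log <- dplyr::bind_cols(
    tibble::tibble(
      Obs = seq_len(n_rows),
      HHMMSS = sprintf("10:%02d:%02d", (seq_len(n_rows) - 1) %/% 60,
                       (seq_len(n_rows) - 1) %% 60),
      Area = g$area_cm2
    ),
    dplyr::mutate(draws, dplyr::across(dplyr::everything(), ~ round(.x, 4)))
  )
  areas <- if (is.null(al_cm2)) NULL else
    tibble::tibble(label = seq_len(n_rows), AL_cm2 = al_cm2)
  structure(list(log = log, areas = areas, gasket = g), class = "synth_gas_log")
}

#' Write a synthetic log as tab-delimited instrument-export text
#'
#' Emits two banner lines before the header, as instrument exports do, and
#' fixed four-decimal formatting so the same seed always produces byte
#' identical files.
#'
#' @param x A [synth_gas_log()] result.
#' @param path Output path for the log; the area annotation (when present) is
#'   written next to it as `<path>.areas.csv`.
#' @return `path`, invisibly.
#' @export
write_gas_log <- function(x, path) {
  stopifnot(inherits(x, "synth_gas_log"))
  log <- x$log
  fmt <- vapply(seq_len(nrow(log)), function(i) {
    paste(
      log$Obs[i], log$HHMMSS[i], sprintf("%.4f", log$Area[i]),
      sprintf("%.4f", log$Photo[i]), sprintf("%.4f", log$Cond[i]),
      sprintf("%.4f", log$Trmmol[i]), sprintf("%.4f", log$Ci[i]),
      sprintf("%.4f", log$PhiPS2[i]),
      sep = "\t"
    )
  }, character(1))
  lines <- c(
    "\"Synthetic gas exchange export\"",
    "\"Unit: leafgasket synthetic module\"",
    paste(c("Obs", "HHMMSS", "Area", "Photo", "Cond", "Trmmol", "Ci", "PhiPS2"),
          collapse = "\t"),
    fmt
  )
  writeLines(lines, path)
  if (!is.null(x$areas)) {
    utils::write.csv(x$areas, paste0(path, ".areas.csv"), row.names = FALSE)
  }
  invisible(path)
}

# Run code under a temporary RNG state; restores any prior state after.
with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Run the synthetic method-agreement study
#'
#' Draws a population of synthetic cereal leaves spanning the four blade
#' archetypes at several positions along the blade, renders each under the
#' gasket impression, and estimates the enclosed area both ways: from the
#' mid-chord width (the caliper route) and from the rendered image (the
#' imaging route). This is the package's end-to-end emulation of comparing
#' the two techniques on live plants; feed the result to [area_agreement()].
#'
#' @param seed Base integer seed; each leaf derives its own seed from it.
#' @param n_per_cell Replicate leaves per archetype x position cell (4
#'   archetypes x 5 positions, so the default yields 40 leaves).
#' @param px_per_cm Rendering resolution.
#' @param noise_sd Pixel noise of the rendered scenes.
#' @param positions Blade positions of the aperture centre, as fractions of
#'   blade length.
#' @param gasket A [gasket_spec()] or aperture area in cm^2.
#' @return A tibble with one row per leaf: `archetype`, `position`, `rep`,
#'   `seed`, `truth_cm2` (integration oracle), `wAL_cm2`, `iAL_cm2`.
#' @examples
#' \donttest{
#' study <- agreement_study(seed = 1, n_per_cell = 1)
#' glance(area_agreement(study))
#' }
#' @export
agreement_study <- function(seed = 1, n_per_cell = 2, px_per_cm = 100,
                            noise_sd = 0,
                            positions = c(0.3, 0.4, 0.5, 0.6, 0.7),
                            gasket = gasket_preset("6400-40")) {
  presets <- leaf_presets()
  g <- as_gasket(gasket)
  grid <- expand.grid(i = seq_len(nrow(presets)),
                      pos_i = seq_along(positions),
                      rep = seq_len(n_per_cell))
  purrr::pmap_dfr(grid, function(i, pos_i, rep) {
    p <- presets[i, ]
    pos <- positions[pos_i]
    leaf_seed <- (abs(seed) %% 1e5) * 10000 + i * 1000 + pos_i * 100 + rep
    leaf <- synth_leaf(p$family, p$base_width_cm, p$taper, p$length_cm,
                       seed = leaf_seed)
    sc <- render_scene(leaf, gasket = g, center_s = pos * p$length_cm,
                       px_per_cm = px_per_cm, noise_sd = noise_sd,
                       seed = leaf_seed)
    ia <- image_based_area(sc$image, gasket = g)
    tibble::tibble(
      archetype = p$archetype, position = pos, rep = rep, seed = leaf_seed,
      truth_cm2 = sc$ground_truth$true_enclosed_area_cm2,
      wAL_cm2 = width_based_area(sc$ground_truth$mid_chord_width_cm, gasket = g),
      iAL_cm2 = ia$area_cm2
    )
  })
}
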