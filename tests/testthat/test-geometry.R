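test_that("aperture radius inverts the disc area relation", {
  expect_equal(radius_from_area(pi), 1)
  expect_equal(radius_from_area(2), 0.7978846, tolerance = 1e-6)
  expect_equal(gasket_spec(2)$radius_cm, sqrt(2 / pi), tolerance = 1e-12)
  expect_error(radius_from_area(0), "invalid-gasket")
  expect_error(radius_from_area(-1), "invalid-gasket")
  expect_error(gasket_spec(NA_real_), "invalid-gasket")
})

test_that("central angle spans the diameter-to-tangent range and is monotone", {
  expect_equal(central_angle(0, 1), 180)
  expect_equal(central_angle(1, 1), 0)
  r <- sqrt(2 / pi)
  expect_equal(central_angle(0.25, r), 2 * acos(0.25 / r) * 180 / pi)
  expect_equal(central_angle(0.25, r), 143.4801, tolerance = 1e-4)
  y <- seq(0, r, length.out = 50)
  expect_true(all(diff(central_angle(y, r)) < 0))
  expect_error(central_angle(-0.1, 1), "invalid-width")
  expect_error(central_angle(1.1, 1), "invalid-width")
})

test_that("sector, triangle and segment areas match their closed forms", {
  expect_equal(sector_area(1, 360), pi)
  expect_equal(sector_area(1, 0), 0)
  expect_equal(sector_area(2, 90), pi)
  expect_error(sector_area(1, 361), "invalid-angle")
  expect_error(sector_area(1, -1), "invalid-angle")

  expect_equal(isosceles_triangle_area(0, 1), 0)
  expect_equal(isosceles_triangle_area(1, 1), 0)
  expect_equal(isosceles_triangle_area(1 / sqrt(2), 1), 0.5)

  r <- sqrt(2 / pi)
  expect_equal(segment_area(r, r), 0)
  expect_equal(segment_area(0, 1), pi / 2)
  expect_equal(segment_area(0.25, r), 0.607685, tolerance = 1e-5)
})

test_that("sector = triangle + segment across the full half-width range", {
  r <- sqrt(2 / pi)
  y <- seq(0, r, length.out = 1000)
  lhs <- sector_area(r, central_angle(y, r))
  rhs <- isosceles_triangle_area(y, r) + segment_area(y, r)
  expect_true(all(abs(lhs - rhs) < 1e-10))
})

test_that("width-based area matches frozen oracle values and the closed form", {
  expect_equal(width_based_area(0), 0)
  expect_equal(width_based_area(0.5), 0.784630, tolerance = 1e-5)
  expect_equal(width_based_area(1.0), 1.484097, tolerance = 1e-5)
  # leaf exactly spanning the 2 cm^2 aperture
  expect_warning(full <- width_based_area(2 * sqrt(2 / pi)), "clipped")
  expect_equal(full, 2)

  # stepwise construction == single closed form over a (W, A_G) grid
  for (AG in c(0.8, 2, 3.7)) {
    r <- sqrt(AG / pi)
    W <- seq(0, 2 * r, length.out = 41)
    expect_true(all(abs(width_based_area(W[-41], gasket = AG) -
                          closed_form_wal(W[-41], AG)) < 1e-10))
  }
})

test_that("width-based area is strictly increasing and continuous at endpoints", {
  r <- sqrt(2 / pi)
  W <- seq(1e-9, 2 * r - 1e-9, length.out = 500)
  a <- width_based_area(W)
  expect_true(all(diff(a) > 0))
  expect_lt(a[1], 1e-6)
  expect_gt(a[500], 2 - 1e-6)
})

test_that("width-based area agrees with the Monte-Carlo oracle within 3 SE", {
  withr::with_seed(11, {
    pairs <- data.frame(AG = runif(8, 0.5, 4))
    pairs$W <- runif(8, 0.05, 0.95) * 2 * sqrt(pairs$AG / pi)
  })
  for (i in seq_len(nrow(pairs))) {
    mc <- mc_strip_area(pairs$W[i], pairs$AG[i], n = 1e6, seed = 100 + i)
    expect_lt(abs(width_based_area(pairs$W[i], gasket = pairs$AG[i]) - mc$est),
              3 * mc$se)
  }
})

test_that("width_area reports the full construction consistently", {
  expect_warning(res <- width_area(c(0.5, 1.0, 1.8)), "clipped")
  expect_s3_class(res, "tbl_df")
  expect_equal(res$half_width_y[1:2], c(0.25, 0.5))
  expect_equal(res$segment_area + res$triangle_area, res$sector_area,
               tolerance = 1e-10)
  expect_true(all(res$enclosed_area_wAL >= 0 & res$enclosed_area_wAL <= 2))
  expect_true(all(res$central_angle_theta >= 0 & res$central_angle_theta <= 180))
  expect_equal(res$clipped, c(FALSE, FALSE, TRUE))
  expect_equal(res$enclosed_area_wAL[3], 2) # clipped to the aperture area

  # mm input converts at the boundary
  expect_equal(width_area(10, units = "mm")$enclosed_area_wAL,
               width_based_area(1.0))
  expect_error(width_area(-1), "invalid-width")
})

test_that("uncorrected error follows the area-ratio identity", {
  expect_equal(uncorrected_error_percent(2), 0)
  expect_equal(uncorrected_error_percent(1), 100)
  expect_equal(uncorrected_error_percent(0.5), 300)
  al <- seq(0.2, 2, length.out = 50)
  expect_true(all(diff(uncorrected_error_percent(al)) < 0))
  expect_error(uncorrected_error_percent(0), "invalid-area")
})
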