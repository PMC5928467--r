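test_that("width profiles honour their family definitions", {
  leaf <- synth_leaf("constant", base_width_cm = 1)
  expect_equal(leaf_width_at(leaf, c(0, 5, 20)), c(1, 1, 1))
  expect_equal(leaf_width_at(leaf, c(-0.1, 20.1)), c(0, 0))

  lin <- synth_leaf("linear", base_width_cm = 1, taper = 1, length_cm = 10)
  expect_equal(leaf_width_at(lin, c(0, 5, 10)), c(1, 0.5, 0))

  lan <- synth_leaf("lanceolate", base_width_cm = 1, taper = 1, length_cm = 10)
  expect_equal(leaf_width_at(lan, c(0, 5, 10)), c(1, 0.75, 0))
  # quadratic taper: margins neither straight nor parallel
  s <- seq(0, 10, by = 0.5)
  expect_false(isTRUE(all.equal(diff(leaf_width_at(lan, s)),
                                rep(diff(leaf_width_at(lan, s))[1], 20))))
})

test_that("leaf generation is deterministic per seed and validates parameters", {
  a <- synth_leaf("lanceolate", seed = 5)
  b <- synth_leaf("lanceolate", seed = 5)
  expect_identical(a, b)
  c <- synth_leaf("lanceolate", seed = 6)
  expect_false(a$base_width_cm == c$base_width_cm)
  expect_error(synth_leaf("linear", base_width_cm = 0), "parameter error")
  expect_error(synth_leaf("linear", base_width_cm = 2.5), "parameter error")
  expect_error(synth_leaf("linear", taper = -1), "parameter error")
})

test_that("integration oracle reproduces the width formula for parallel margins", {
  for (w in seq(0.1, 1.5, length.out = 20)) {
    leaf <- synth_leaf("constant", base_width_cm = min(w, 2))
    gt <- true_enclosed_area(leaf)
    expect_equal(gt$true_enclosed_area_cm2, width_based_area(w),
                 tolerance = 1e-6)
    expect_lt(gt$integration_error_cm2, 1e-5)
  }
  # full coverage and empty limits
  wide <- synth_leaf("constant", base_width_cm = 1.99)
  expect_equal(true_enclosed_area(wide)$true_enclosed_area_cm2, 2,
               tolerance = 1e-9)
  tip <- synth_leaf("linear", base_width_cm = 1, taper = 1, length_cm = 10)
  expect_equal(true_enclosed_area(tip, center_s = 30)$true_enclosed_area_cm2, 0)
})

test_that("width formula tracks the oracle within 5% for gently tapering blades", {
  # taper producing <= 10% width change across the aperture chord
  presets <- leaf_presets()
  for (i in seq_len(nrow(presets))) {
    p <- presets[i, ]
    for (pos in c(0.3, 0.5, 0.7)) {
      leaf <- synth_leaf(p$family, p$base_width_cm, p$taper, p$length_cm)
      gt <- true_enclosed_area(leaf, center_s = pos * p$length_cm)
      wal <- width_based_area(gt$mid_chord_width_cm)
      expect_lt(abs(wal - gt$true_enclosed_area_cm2) /
                  gt$true_enclosed_area_cm2, 0.05)
    }
  }
})

test_that("rendered scenes are deterministic and validate resolution", {
  leaf <- synth_leaf("constant", base_width_cm = 0.8)
  a <- render_scene(leaf, px_per_cm = 60, noise_sd = 0.05, seed = 3)
  b <- render_scene(leaf, px_per_cm = 60, noise_sd = 0.05, seed = 3)
  expect_identical(a$image, b$image)
  expect_error(render_scene(leaf, px_per_cm = 10), "resolution error")
})

test_that("rendered pixel-count area converges to ground truth with resolution", {
  leaf <- synth_leaf("lanceolate", base_width_cm = 0.7, length_cm = 25)
  errs <- vapply(c(50, 100, 200), function(ppc) {
    sc <- render_scene(leaf, px_per_cm = ppc)
    ia <- image_based_area(sc$image)
    abs(ia$area_cm2 - sc$ground_truth$true_enclosed_area_cm2) /
      sc$ground_truth$true_enclosed_area_cm2
  }, numeric(1))
  expect_lt(errs[2], 0.01)
  expect_lt(errs[3], 0.01)
  expect_lt(errs[3], errs[1] + 1e-4)
})

test_that("synthetic logs are plausible, deterministic and round-trip", {
  lg <- synth_gas_log(10, seed = 2)
  expect_equal(nrow(lg$log), 10)
  expect_true(all(lg$log$Photo >= 2 & lg$log$Photo <= 25))
  expect_true(all(lg$log$Cond >= 0.05 & lg$log$Cond <= 0.5))
  expect_true(all(lg$log$PhiPS2 >= 0 & lg$log$PhiPS2 <= 1))
  expect_true(all(lg$log$Area == 2))

  p1 <- withr::local_tempfile(fileext = ".txt")
  p2 <- withr::local_tempfile(fileext = ".txt")
  write_gas_log(lg, p1)
  write_gas_log(synth_gas_log(10, seed = 2), p2)
  expect_identical(readLines(p1), readLines(p2)) # byte-identical per seed

  parsed <- read_gas_log(p1)
  expect_equal(nrow(parsed), 10)
  expect_equal(parsed$Photo, lg$log$Photo, tolerance = 1e-9)
  expect_equal(parsed$PhiPS2, lg$log$PhiPS2, tolerance = 1e-9)

  expect_error(synth_gas_log(3, al_cm2 = c(1, 2)), "parameter error")
  expect_error(synth_gas_log(0), "parameter error")
})
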