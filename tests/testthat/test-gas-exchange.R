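test_that("instrument logs round-trip through banner-tolerant parsing", {
  lg <- synth_gas_log(10, seed = 4, al_cm2 = runif(10, 1, 2))
  path <- withr::local_tempfile(fileext = ".txt")
  write_gas_log(lg, path)

  parsed <- read_gas_log(path) # file starts with two banner lines
  expect_equal(nrow(parsed), 10)
  expect_equal(parsed$Cond, lg$log$Cond, tolerance = 1e-9)
  expect_equal(parsed$.row, 1:10)
  expect_true(file.exists(paste0(path, ".areas.csv")))

  # comma-delimited dialect parses identically
  csv <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(lg$log, csv)
  expect_equal(read_gas_log(csv)$Photo, parsed$Photo)

  # a log missing a mandatory column is a schema error naming what was found
  broken <- withr::local_tempfile(fileext = ".txt")
  readr::write_tsv(dplyr::select(lg$log, -Cond), broken)
  expect_error(read_gas_log(broken), "schema error")
})

test_that("correction is exact area rescaling with flux conservation", {
  log <- tibble::tibble(Obs = 1:3, Area = 2, Photo = c(10, 5, 20),
                        Cond = c(0.2, 0.1, 0.4), Trmmol = c(2, 1, 4),
                        Ci = c(280, 300, 250), PhiPS2 = c(0.6, 0.7, 0.65))
  out <- correct_gas_exchange(log, area = 1.484097)
  expect_equal(out$corr_factor, rep(2 / 1.484097, 3))
  expect_equal(out$Photo_corr[1], 13.4762, tolerance = 1e-4)
  expect_equal(out$Cond_corr[1], 0.269524, tolerance = 1e-5)
  # molar flux conservation: corrected rate x A_L == original rate x S
  expect_equal(out$Photo_corr * out$AL_cm2, out$Photo * out$Area,
               tolerance = 1e-9)
  expect_equal(out$Trmmol_corr * out$AL_cm2, out$Trmmol * out$Area,
               tolerance = 1e-9)
  # Ci and PhiPSII pass through untouched
  expect_equal(out$Ci, log$Ci)
  expect_equal(out$PhiPS2, log$PhiPS2)
  expect_true(attr(out, "ci_uncorrected"))

  # full coverage is the identity
  id <- correct_gas_exchange(log, area = 2)
  expect_equal(id$Photo_corr, log$Photo)
  # half coverage doubles per-area rates
  half <- correct_gas_exchange(log, area = 1)
  expect_equal(half$Photo_corr, 2 * log$Photo)
})

test_that("iWUE is the PN/gs ratio and invariant under correction", {
  expect_equal(iwue(10, 0.2), 50)
  expect_equal(iwue(0, 0.2), 0)
  expect_error(iwue(10, 0), "undefined-iwue")

  lg <- synth_gas_log(25, seed = 9)
  out <- correct_gas_exchange(lg$log, area = runif(25, 0.5, 2))
  expect_equal(out$iWUE_corr, out$iWUE, tolerance = 1e-12)
  expect_equal(out$iWUE, out$Photo / out$Cond, tolerance = 1e-12)
})

test_that("correction factor is monotone in A_L and invertible", {
  log <- synth_gas_log(1, seed = 1)$log
  al <- seq(0.2, 2, length.out = 30)
  fac <- vapply(al, function(a) correct_gas_exchange(log, a)$corr_factor,
                numeric(1))
  expect_true(all(diff(fac) < 0))

  # correcting then un-correcting recovers the original to <= 1 ulp drift
  out <- correct_gas_exchange(log, area = 1.3)
  back <- out$Photo_corr * (1.3 / out$Area)
  expect_equal(back, log$Photo, tolerance = 1e-15)
})

test_that("invalid and oversized areas are refused", {
  log <- synth_gas_log(2, seed = 1)$log
  expect_error(correct_gas_exchange(log, area = 0), "invalid-area")
  expect_error(correct_gas_exchange(log, area = -1), "invalid-area")
  expect_error(correct_gas_exchange(log, area = 2.5), "oversized-area")
  expect_error(correct_gas_exchange(log, area = c(1, 2, 3)), "invalid-area")
})

test_that("batch log correction joins widths by label and reports", {
  lg <- synth_gas_log(4, seed = 7)
  path <- withr::local_tempfile(fileext = ".txt")
  write_gas_log(lg, path)

  widths <- tibble::tibble(label = 1:4, width_cm = c(0.5, 0.8, 1.0, 1.3))
  res <- correct_log(path, widths)
  expect_s3_class(res, "corrected_log")
  expect_equal(res$data$AL_cm2, width_based_area(widths$width_cm))
  expect_equal(glance(res), res$report)
  expect_equal(res$report$n, 4)
  expect_equal(res$report$max_factor, 2 / width_based_area(0.5))

  # identity when A_L == S everywhere
  same <- correct_log(path, 2)
  expect_equal(same$data$Photo_corr, same$data$Photo)
  expect_equal(same$report$max_uncorrected_error_pct, 0)

  # output file is written and source preserved
  out_path <- withr::local_tempfile(fileext = ".tsv")
  correct_log(path, 2, out = out_path)
  expect_true(file.exists(out_path))
  expect_identical(readLines(path)[1], "\"Synthetic gas exchange export\"")

  # unmatched labels name the offenders, in both directions
  extra <- tibble::tibble(label = c(1:4, 99), width_cm = rep(1, 5))
  expect_error(correct_log(path, extra), "join error.*99")
  expect_error(correct_log(path, widths[1:3, ]), "join error.*4")
})
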