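test_that("compression and scanning-reduction arithmetic is exact", {
  full <- compression_and_reduction(180, 180, 15)
  expect_identical(full$cr, 1)
  expect_identical(full$point_scan_factor, 2700)
  expect_identical(full$line_scan_factor, 15)
  expect_equal(compression_and_reduction(180, 20, 15)$cr, 9)
  expect_equal(compression_and_reduction(64, 64, 4)$cr, 1)
  expect_error(compression_and_reduction(0, 10, 5))
})

test_that("light throughput follows both closed forms", {
  expect_equal(throughput("sflim", grating_efficiency_chi = 0.75,
                          quantum_efficiency_eta = 0.3, K = 15), 0.015)
  # the pupil demagnification plays no role in the dispersed mode
  z1 <- throughput("sflim", grating_efficiency_chi = 0.5,
                   quantum_efficiency_eta = 0.4, K = 10,
                   pupil_demag_r = 0.1)
  z2 <- throughput("sflim", grating_efficiency_chi = 0.5,
                   quantum_efficiency_eta = 0.4, K = 10,
                   pupil_demag_r = 10)
  expect_identical(z1, z2)
  # direct mode: p = 26.2 um, kappa = 0.5, r = 0.1 reproduce the system's
  # 0.01 throughput when D0 solves the formula (13.1 mm)
  D0_um <- 26.2 * 0.5 / (0.01 * 0.1)
  expect_equal(D0_um, 13100)
  expect_equal(throughput("flim", pixel_pitch_p = 26.2,
                          fill_factor_kappa = 0.5,
                          full_aperture_D0 = D0_um, pupil_demag_r = 0.1),
               0.01, tolerance = 1e-12)
  expect_error(throughput("flim", pixel_pitch_p = 26.2), "needs")
})

test_that("width deconvolution implements the discrete convolution rule", {
  # two-factor: a 5-pixel total with a 4-pixel bead leaves 2 pixels
  expect_equal(deconvolved_width(5, 4)$width, 2)
  # three-factor composition: components (7, 7, 48) convolve to width 60
  expect_equal(convolved_width(c(7, 7, 48)), 60)
  expect_equal(deconvolved_width(60, c(7, 7))$width, 48)
  # sequential two-factor deconvolution equals the three-factor formula
  step1 <- deconvolved_width(60, 7)$width
  expect_equal(deconvolved_width(step1, 7)$width, 48)
  # boundary and infeasible cases
  expect_equal(deconvolved_width(3, 4)$width, 0)
  expect_error(deconvolved_width(2, 4), "infeasible")
  # fractional widths are preserved exactly alongside the pixel rounding
  w <- deconvolved_width(4.6 / 0.9, 4)
  expect_equal(w$width, 4.6 / 0.9 - 3, tolerance = 1e-12)
  expect_equal(w$width_px, 2)
})

test_that("projection centres are localized to sub-pixel accuracy", {
  N <- 41
  g <- lift_geometry(N = N, K = 4, Ntheta = 12)
  pin <- forward_sinogram(impulse_image(N), g)
  cal <- calibrate_projection_center(pin)
  expect_equal(cal$yp0, rep((N - 1) / 2, nrow(cal)), tolerance = 0.1)

  # known per-view shifts are recovered
  shifted <- pin
  offsets <- c(1.5, -2, 0.5, 3)[shifted$plan$view]
  for (r in seq_len(nrow(shifted$plan))) {
    shifted$rows[r, ] <- flimtomo:::shift_vector(shifted$rows[r, ],
                                                 -offsets[r])
  }
  cal2 <- calibrate_projection_center(shifted)
  expect_equal(cal2$yp0 - cal$yp0, offsets, tolerance = 0.1)

  # translation equivariance: shifting every row by c shifts every centre
  allsh <- pin
  for (r in seq_len(nrow(allsh$plan))) {
    allsh$rows[r, ] <- flimtomo:::shift_vector(allsh$rows[r, ], -2)
  }
  cal3 <- calibrate_projection_center(allsh)
  expect_equal(cal3$yp0 - cal$yp0, rep(2, nrow(cal)), tolerance = 0.05)

  dead <- pin; dead$rows[3, ] <- 0
  expect_error(calibrate_projection_center(dead), "missing signal.*row 3")
})

test_that("spectral-axis fits recover sampling slopes", {
  px <- c(0, 250, 500, 750, 1000)
  cal <- fit_spectral_axis(tibble::tibble(pixel = px,
                                          wavelength_nm = 500 + 0.14 * px))
  expect_equal(cal$slope_nm_per_px, 0.14, tolerance = 1e-12)
  two <- fit_spectral_axis(tibble::tibble(pixel = c(10, 20),
                                          wavelength_nm = c(520, 531)))
  expect_equal(two$slope_nm_per_px, 1.1, tolerance = 1e-12)
  expect_error(fit_spectral_axis(tibble::tibble(pixel = 1:3,
                                                wavelength_nm = rep(5, 3))),
               "distinct")
  # Monte Carlo: slope within 3 standard errors under pixel noise
  set.seed(31)
  hits <- vapply(1:100, function(i) {
    noisy <- tibble::tibble(pixel = px + rnorm(5, sd = 0.3),
                            wavelength_nm = 500 + 0.14 * px)
    fitn <- fit_spectral_axis(noisy)
    se <- tidy(fitn)$std_error[2]
    abs(fitn$slope_nm_per_px - 0.14) <= 3 * se
  }, logical(1))
  expect_gt(mean(hits), 0.9)
})
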