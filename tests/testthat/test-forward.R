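test_that("rotation honours its stated conventions", {
  img <- smooth_image(21, seed = 2)
  # identity at 0 degrees (and multiples of 360)
  expect_identical(rotate_image(img, 0), img)
  expect_identical(rotate_image(img, 720), img)
  # impulse at (row +5, col 0) from centre moves to (0, +5) under a 90-degree
  # turn (counter-clockwise as displayed, rows increasing downward)
  imp <- impulse_image(33, drow = 5, dcol = 0)
  r <- rotate_image(imp, 90)
  peak <- which(r == max(r), arr.ind = TRUE)
  expect_equal(unname(peak[1, ]), c(17, 22))  # centre 17: offset (0, +5)
})

test_that("rotation matches a naive per-pixel resampling oracle", {
  ph <- make_phantom("shepp_logan", N = 41)
  for (theta in c(37, -12.3, 101)) {
    got <- rotate_image(ph, theta)
    want <- rotate_oracle(ph, theta)
    expect_lt(max(abs(got - want)), 1e-6 * max(ph))
  }
})

test_that("back rotation recovers the image on the inscribed disk", {
  img <- smooth_image(41, seed = 4)
  back <- rotate_image(rotate_image(img, 33), -33)
  c0 <- 21
  xs <- matrix(1:41, 41, 41, byrow = TRUE); ys <- matrix(1:41, 41, 41)
  disk <- (xs - c0)^2 + (ys - c0)^2 <= 14^2
  expect_lt(max(abs(back[disk] - img[disk])), 0.1 * max(img))
})

test_that("en-face projection is a mass-conserving column sum", {
  ones <- matrix(1, 8, 8)
  expect_equal(project_enface(ones), rep(8, 8))
  imp <- impulse_image(15, 0, 3)
  pr <- project_enface(imp)
  expect_equal(which(pr > 0), 8 + 3)
  set.seed(5)
  rnd <- matrix(runif(100), 10, 10)
  expect_equal(sum(project_enface(rnd)), sum(rnd))
})

test_that("shear_shift implements the 1-D projection shearing formula", {
  expect_equal(shear_shift(2.5, 1, 0, 90), 2.5)
  expect_equal(shear_shift(0, 0.3, -0.7, 123), 0)
  expect_equal(shear_shift(2, 0.5, 0.5, 45), 0)
  # generic value against the formula written out longhand
  expect_equal(shear_shift(1.3, 0.4, -0.2, 30),
               1.3 * 0.4 * sin(pi / 6) + 1.3 * 0.2 * cos(pi / 6))
})

test_that("render_perspective shifts by (s*u, s*v) with zero fill", {
  h <- smooth_image(19, seed = 6)
  expect_identical(render_perspective(h, c(0.7, -0.3), 0), h)
  imp <- impulse_image(21)
  moved <- render_perspective(imp, c(1, 0), 3)
  peak <- which(moved == max(moved), arr.ind = TRUE)
  expect_equal(unname(peak[1, ]), c(11, 14))  # 3 pixels along x (columns)
  # disparity between opposite views is 2s pixels
  a <- render_perspective(imp, c(-1, 0), 2)
  b <- render_perspective(imp, c(+1, 0), 2)
  pa <- which(a == max(a), arr.ind = TRUE)[1, 2]
  pb <- which(b == max(b), arr.ind = TRUE)[1, 2]
  expect_equal(unname(pb - pa), 4)
})

test_that("forward projection follows the sheared-sinusoid trajectory", {
  N <- 33
  g <- lift_geometry(N = N, K = 3, Ntheta = 12)
  plan <- angle_plan(g)
  h <- impulse_image(N, drow = 3, dcol = 4)
  s <- 2.5
  f <- forward_sinogram(h, g, depths_um = s / g$shear_per_um)
  for (r in seq_len(nrow(plan))) {
    pr <- f$rows[r, ]
    centroid <- sum((0:(N - 1)) * pr) / sum(pr) - (N - 1) / 2
    th <- plan$angle_deg[r] * pi / 180
    base <- 4 * cos(th) + 3 * sin(th)
    predicted <- base + detector_shift(s, plan$u[r], plan$v[r],
                                       plan$angle_deg[r])
    expect_equal(centroid, predicted, tolerance = 1e-10)
  }
  # and matches the explicit render -> rotate -> project chain row by row
  for (r in c(1, 6, 12)) {
    chain <- project_enface(rotate_image(
      render_perspective(h, c(plan$u[r], plan$v[r]), s), plan$angle_deg[r]))
    expect_equal(which.max(f$rows[r, ]), which.max(chain))
  }
})

test_that("zero scenes, centred points and linearity behave as an operator", {
  N <- 32
  g <- lift_geometry(N = N, K = 4, Ntheta = 16)
  zero <- forward_sinogram(matrix(0, N, N), g)
  expect_true(all(zero$rows == 0))

  centre <- forward_sinogram(impulse_image(N - 1), lift_geometry(N - 1, 4, 16))
  peaks <- apply(centre$rows, 1, which.max)
  expect_true(all(peaks == (N - 1 + 1) / 2))

  h1 <- smooth_image(N, 7); h2 <- smooth_image(N, 8)
  f1 <- forward_sinogram(h1, g)$rows
  f2 <- forward_sinogram(h2, g)$rows
  f12 <- forward_sinogram(2.5 * h1 - 0.5 * h2, g)$rows
  expect_rel_equal(f12, 2.5 * f1 - 0.5 * f2, 1e-10)
})

test_that("each sinogram row conserves in-field photon mass", {
  N <- 33
  g <- lift_geometry(N = N, K = 5, Ntheta = 20)
  h <- matrix(0, N, N)
  h[13:21, 13:21] <- smooth_image(9, 9)   # content well inside the field
  f <- forward_sinogram(h, g)
  expect_equal(rowSums(f$rows), rep(sum(h), nrow(f$rows)), tolerance = 1e-12)
})

test_that("multi-plane scenes superpose and mismatched sizes error", {
  N <- 25
  g <- lift_geometry(N = N, K = 3, Ntheta = 10)
  a <- impulse_image(N, 0, 5); b <- impulse_image(N, 4, -2)
  two <- array(c(a, b), c(N, N, 2))
  f2 <- forward_sinogram(two, g, depths_um = c(-4, 4))
  fa <- forward_sinogram(a, g, depths_um = -4)
  fb <- forward_sinogram(b, g, depths_um = 4)
  expect_rel_equal(f2$rows, fa$rows + fb$rows, 1e-12)
  expect_error(forward_sinogram(matrix(0, 10, 10), g), "does not match")
})

test_that("time-resolved forward projection is separable per bin", {
  N <- 24
  scene <- make_phantom("beads3d", N = N, seed = 3, n_beads = c(2, 1, 1),
                        diameters_um = c(3, 4, 5), time_bins = 6,
                        depths_um = 0)
  g <- lift_geometry(N = N, K = 3, Ntheta = 8)
  ft <- forward_sinogram(scene, g)
  expect_equal(dim(ft$rows), c(8, N, 6))
  for (b in c(1, 4, 6)) {
    fb <- forward_sinogram(scene$voxels[, , 1, b], g)
    expect_rel_equal(ft$rows[, , b], fb$rows, 1e-12)
  }
})

test_that("sinograms tidy into long row/angle tables", {
  g <- lift_geometry(N = 8, K = 2, Ntheta = 4)
  f <- forward_sinogram(smooth_image(8), g)
  td <- tidy(f)
  expect_equal(nrow(td), 4 * 8)
  expect_named(td, c("row", "view", "angle_deg", "pixel", "value"))
  expect_equal(td$value[td$row == 2], unname(f$rows[2, ]))
})
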