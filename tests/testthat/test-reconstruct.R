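test_that("refocusing shifts rows consistently with the forward shear", {
  N <- 33
  g <- lift_geometry(N = N, K = 5, Ntheta = 16)
  h <- impulse_image(N, 2, -3)
  s <- 2.2
  f_d <- forward_sinogram(h, g, depths_um = s / g$shear_per_um)
  f_0 <- forward_sinogram(h, g, depths_um = 0)

  # s = 0 is the identity
  expect_identical(refocus_sinogram(f_d, 0)$rows, f_d$rows)

  # refocusing with the matching shear aligns peaks with the in-focus case
  ref <- refocus_sinogram(f_d, s)
  centroid <- function(v) sum(seq_along(v) * v) / sum(v)
  for (r in seq_len(nrow(ref$plan))) {
    expect_lte(abs(centroid(ref$rows[r, ]) - centroid(f_0$rows[r, ])),
               0.5 + 1e-9)
  }

  # round trip: +s then -s restores interior pixels; the tolerance covers
  # double linear interpolation on the pixel-level ripple the pixel-driven
  # projector leaves in oblique rows
  blob <- matrix(0, N, N)
  blob[13:21, 13:21] <- outer(exp(-(-4:4)^2 / 6), exp(-(-4:4)^2 / 6))
  f_b <- forward_sinogram(blob, g, depths_um = 0)
  back <- refocus_sinogram(refocus_sinogram(f_b, +s), -s)
  interior <- 8:(N - 8)
  expect_lt(max(abs(back$rows[, interior] - f_b$rows[, interior])),
            0.12 * max(f_b$rows))
  # mass along each row is conserved by the round trip
  expect_equal(rowSums(back$rows), rowSums(f_b$rows), tolerance = 0.02)
})

test_that("FBP reconstructs points at the centre and acts linearly", {
  N <- 31
  g <- lift_geometry(N = N, K = 1, Ntheta = N)
  f <- forward_sinogram(impulse_image(N), g)
  rec <- fbp_reconstruct(f)
  expect_equal(unname(which(rec == max(rec), arr.ind = TRUE)[1, ]), c(16, 16))

  h1 <- smooth_image(N, 11); h2 <- smooth_image(N, 12)
  f1 <- forward_sinogram(h1, g); f2 <- forward_sinogram(h2, g)
  fsum <- f1; fsum$rows <- f1$rows + f2$rows
  expect_rel_equal(fbp_reconstruct(fsum),
                   fbp_reconstruct(f1) + fbp_reconstruct(f2), 1e-8)

  one_angle <- lift_geometry(N = N, K = 1, Ntheta = 1)
  expect_error(fbp_reconstruct(forward_sinogram(h1, one_angle)),
               "insufficient angles")
})

test_that("FBP agrees with the scikit-image reference on identical input", {
  skip_if_not(nzchar(Sys.which("python")), "python not on PATH")
  N <- 129   # odd size so both implementations share the same centre pixel
  ph <- make_phantom("shepp_logan", N = N)
  g <- lift_geometry(N = N, K = 1, Ntheta = N)
  f <- forward_sinogram(ph, g)
  mine <- fbp_reconstruct(f, filter = "hann")
  psnr_mine <- image_metrics(mine, ph, data_range = 1)$psnr_db

  td <- withr::local_tempdir()
  utils::write.table(f$rows, file.path(td, "sino.csv"), sep = ",",
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(ph, file.path(td, "ph.csv"), sep = ",",
                     row.names = FALSE, col.names = FALSE)
  writeLines(as.character(angle_plan(g)$angle_deg), file.path(td, "ang.txt"))
  script <- sprintf('
import numpy as np
from skimage.transform import iradon
sino = np.loadtxt(r"%s/sino.csv", delimiter=",")
ph = np.loadtxt(r"%s/ph.csv", delimiter=",")
ang = np.loadtxt(r"%s/ang.txt")
# this package rotates counter-clockwise as displayed; skimage radon uses the
# opposite sign, hence theta = -angles
rec = iradon(sino.T, theta=-ang, filter_name="hann", circle=False,
             output_size=ph.shape[0], interpolation="linear")
rmse = np.sqrt(((rec - ph) ** 2).mean())
print(20 * np.log10(1.0 / rmse))
', td, td, td)
  out <- system2("python", "-", input = script, stdout = TRUE, stderr = FALSE)
  psnr_ref <- as.numeric(tail(out, 1))
  expect_true(is.finite(psnr_ref))
  expect_lt(abs(psnr_mine - psnr_ref), 0.5)
})

test_that("FISTA at mu = 0 matches conjugate-gradient least squares", {
  N <- 24
  ph <- make_phantom("shepp_logan", N = N)
  g <- lift_geometry(N = N, K = 5, Ntheta = 3 * N)  # overdetermined
  A <- lift_system_matrix(g, 0)
  f <- forward_sinogram(ph, g)
  y <- as.vector(t(f$rows))
  rec <- suppressWarnings(fista_reconstruct(
    f, 0, recon_config(mu = 0, max_iters = 4000, rel_tol = 1e-12,
                       nonneg = FALSE), sysmat = A))
  # noiseless data fit
  expect_lt(sqrt(sum((y - as.vector(A %*% as.vector(rec)))^2)) /
              sqrt(sum(y^2)), 1e-3)
  xc <- cgls_solve(A, y, 800)
  expect_rel_equal(as.vector(rec), xc, 0.01)
})

test_that("the FISTA objective trace is monotone and attributes are set", {
  N <- 32
  ph <- make_phantom("usaf_bars", N = N)
  g <- lift_geometry(N = N, K = 4, Ntheta = 8)
  f <- forward_sinogram(ph, g)
  rec <- suppressWarnings(fista_reconstruct(
    f, 0, recon_config(mu = 0.05, max_iters = 40, rel_tol = 1e-12)))
  obj <- attr(rec, "objective")
  expect_true(all(diff(obj) <= 1e-9))
  expect_true(all(rec >= 0))
  expect_false(attr(rec, "converged"))
  expect_warning(fista_reconstruct(
    f, 0, recon_config(mu = 0.05, max_iters = 5, rel_tol = 1e-12)),
    "best iterate")
})

test_that("sparse scenes reconstruct well from compressive plans", {
  # scaled-down compressive recovery check (CR = 8 at N = 64)
  N <- 64
  bars <- make_phantom("usaf_bars", N = N)
  g <- lift_geometry(N = N, K = 4, Ntheta = 8)
  f <- forward_sinogram(bars, g)
  rec <- suppressWarnings(fista_reconstruct(
    f, 0, recon_config(mu = 0.05, max_iters = 150, rel_tol = 1e-7)))
  expect_gt(image_metrics(rec, bars, data_range = 1)$ssim, 0.9)
})

test_that("TV denoising reduces noise without destroying structure", {
  set.seed(42)
  clean <- make_phantom("shepp_logan", N = 48)
  noisy <- clean + matrix(rnorm(48 * 48, sd = 0.1), 48, 48)
  den <- tv_denoise(noisy, weight = 0.1)
  expect_lt(mean((den - clean)^2), mean((noisy - clean)^2))
  expect_identical(tv_denoise(noisy, 0), noisy)
})
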