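# Independent oracles and small fixtures shared by the tests.

# Naive per-pixel inverse-mapping bilinear rotation: a deliberately plain
# double loop, independent of the vectorized implementation it checks.
rotate_oracle <- function(img, theta_deg) {
  N <- nrow(img)
  th <- theta_deg * pi / 180
  ct <- cos(th); st <- sin(th)
  c0 <- (N - 1) / 2
  out <- matrix(0, N, N)
  for (row in 1:N) for (col in 1:N) {
    x <- (col - 1) - c0
    y <- (row - 1) - c0
    sx <- ct * x - st * y + c0
    sy <- st * x + ct * y + c0
    ix <- floor(sx); iy <- floor(sy)
    fx <- sx - ix; fy <- sy - iy
    acc <- 0
    for (dx in 0:1) for (dy in 0:1) {
      px <- ix + dx; py <- iy + dy
      if (px >= 0 && px < N && py >= 0 && py < N) {
        w <- (if (dx == 1) fx else 1 - fx) * (if (dy == 1) fy else 1 - fy)
        acc <- acc + w * img[py + 1, px + 1]
      }
    }
    out[row, col] <- acc
  }
  out
}

# Conjugate-gradient least squares on the normal equations; independent
# solver used as the mu = 0 oracle.
cgls_solve <- function(A, y, n_iter = 500) {
  x <- rep(0, ncol(A))
  r <- y
  s <- as.vector(Matrix::crossprod(A, r))
  p <- s
  g0 <- sum(s^2)
  for (i in seq_len(n_iter)) {
    q <- as.vector(A %*% p)
    alpha <- g0 / sum(q^2)
    x <- x + alpha * p
    r <- r - alpha * q
    s <- as.vector(Matrix::crossprod(A, r))
    g1 <- sum(s^2)
    p <- s + (g1 / g0) * p
    g0 <- g1
    if (g0 < 1e-22) break
  }
  x
}

# impulse image with a unit pixel at a (row, col) offset from the centre
impulse_image <- function(N, drow = 0, dcol = 0) {
  img <- matrix(0, N, N)
  c0 <- (N + 1) / 2
  img[c0 + drow, c0 + dcol] <- 1
  img
}

# small smooth random image (reproducible)
smooth_image <- function(N, seed = 1) {
  set.seed(seed)
  img <- matrix(runif(N * N), N, N)
  k <- exp(-(-3:3)^2 / 4); k <- k / sum(k)
  img <- apply(img, 2, function(col) stats::filter(c(rev(col[1:3]), col, rev(col[N - 2:0])), k, sides = 2)[4:(N + 3)])
  img <- t(apply(img, 1, function(row) stats::filter(c(rev(row[1:3]), row, rev(row[N - 2:0])), k, sides = 2)[4:(N + 3)]))
  img - min(img)
}

# detector-frame shift used by the forward model (documented convention:
# prism angle measured from the projection axis)
detector_shift <- function(s, u, v, theta_deg) {
  shear_shift(s, u, v, theta_deg + 90)
}

expect_rel_equal <- function(a, b, tol) {
  expect_lt(sqrt(sum((a - b)^2)) / max(sqrt(sum(b^2)), 1e-300), tol)
}
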