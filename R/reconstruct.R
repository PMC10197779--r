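# ---- refocusing -----------------------------------------------------------

# linear shift of a vector with zero fill
shift_vector <- function(v, d) {
  if (d == 0) return(v)
  stats::approx(seq_along(v), v, xout = seq_along(v) + d,
                yleft = 0, yright = 0)$y
}

#' Digitally refocus a sinogram onto a shear plane
#'
#' Shifts every sinogram row along its detector axis by the view- and
#' angle-dependent shear displacement so that content at the shear parameter
#' `s` (equivalently depth `d` with `s = s(d)`) is brought into the
#' common focal (d = 0) frame for reconstruction. Sub-pixel shifts use
#' linear interpolation with zero fill; `refocus(-s)` undoes `refocus(+s)`
#' away from the borders.
#'
#' @param f A `lift_sinogram`.
#' @param s Shear parameter in pixels (use [depth_to_shear()] for microns).
#' @return A `lift_sinogram` with shifted rows.
#' @export
refocus_sinogram <- function(f, s) {
  stopifnot(inherits(f, "lift_sinogram"))
  if (s == 0) return(f)
  plan <- f$plan
  rows <- f$rows
  d <- dim(rows)
  shifts <- projection_shift(s, plan$u, plan$v, plan$angle_deg)
  if (length(d) == 2) {
    for (r in seq_len(d[1])) rows[r, ] <- shift_vector(rows[r, ], shifts[r])
  } else {
    nbin <- prod(d[-(1:2)])
    flat <- matrix(rows, nrow = d[1] * d[2], ncol = nbin)
    for (r in seq_len(d[1])) {
      idx <- r + (seq_len(d[2]) - 1L) * d[1]
      flat[idx, ] <- apply(flat[idx, , drop = FALSE], 2,
                           shift_vector, d = shifts[r])
    }
    rows <- array(flat, dim = d)
  }
  out <- f
  out$rows <- rows
  out$meta$refocused_shear <- (f$meta$refocused_shear %||% 0) + s
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- filtered back-projection ---------------------------------------------

# Frequency response of the discrete ramp filter (Kak & Slaney band-limited
# construction), optionally apodized, for padded row length n.
ramp_filter <- function(n, filter = c("hann", "ramp", "none")) {
  filter <- match.arg(filter)
  if (filter == "none") return(rep(1, n))
  # real-space kernel of the band-limited ramp
  f <- numeric(n)
  f[1] <- 0.25
  k <- seq(1, n / 2)
  odd <- k[k %% 2 == 1]
  f[1 + odd] <- -1 / (pi * odd)^2
  f[n + 1 - odd] <- -1 / (pi * odd)^2
  H <- 2 * Re(stats::fft(f))
  if (filter == "hann") {
    # apodize with a Hann window over the frequency axis
    freq <- c(seq(0, n / 2), seq(-n / 2 + 1, -1)) / n
    H <- H * (0.5 + 0.5 * cos(2 * pi * freq))
  }
  H
}

filter_rows <- function(rows, filter) {
  n <- ncol(rows)
  npad <- max(64L, 2L^ceiling(log2(2 * n)))
  H <- ramp_filter(npad, filter)
  padded <- matrix(0, npad, nrow(rows))
  padded[seq_len(n), ] <- t(rows)
  spec <- stats::mvfft(padded) * H
  filt <- Re(stats::mvfft(spec, inverse = TRUE)) / npad
  t(filt[seq_len(n), , drop = FALSE])
}

#' Filtered back-projection reconstruction
#'
#' Reconstructs an image from a (refocused) sinogram by ramp filtering each
#' row and back-projecting along its angle with the exact adjoint of the
#' forward operator. The default Hann apodization tames noise amplification
#' in sparse-view data; `filter = "ramp"` is the unapodized ramp.
#'
#' @param f A `lift_sinogram`.
#' @param s Shear parameter of the plane to reconstruct (the sinogram is
#'   refocused by `s` first); default 0.
#' @param filter `"hann"` (default), `"ramp"` or `"none"`.
#' @param sysmat Optional precomputed `lift_system_matrix(geom, 0)` to reuse
#'   across calls (depth sweeps, per-bin stacks).
#' @return `N x N` image matrix (time/spectral sinograms: an array with the
#'   trailing bin dimensions, each bin reconstructed independently).
#' @export
fbp_reconstruct <- function(f, s = 0, filter = c("hann", "ramp", "none"),
                            sysmat = NULL) {
  stopifnot(inherits(f, "lift_sinogram"))
  filter <- match.arg(filter)
  geom <- f$geom
  if (length(unique(f$plan$angle_deg)) < 2) {
    stop("insufficient angles: filtered back-projection needs at least 2 ",
         "distinct projection angles", call. = FALSE)
  }
  if (s != 0) f <- refocus_sinogram(f, s)
  N <- geom$N
  d <- dim(f$rows)
  Bt <- Matrix::t(sysmat %||% lift_system_matrix(geom, 0))
  scale <- pi / (2 * nrow(f$plan))
  if (length(d) == 2) {
    filt <- filter_rows(f$rows, filter)
    img <- matrix(as.vector(Bt %*% as.vector(t(filt))), N, N) * scale
    img
  } else {
    nbin <- prod(d[-(1:2)])
    out <- array(0, dim = c(N, N, d[-(1:2)]))
    flat <- matrix(f$rows, nrow = d[1] * d[2], ncol = nbin)
    vecs <- matrix(0, d[1] * d[2], nbin)
    for (b in seq_len(nbin)) {
      rows_b <- matrix(flat[, b], d[1], d[2])
      vecs[, b] <- as.vector(t(filter_rows(rows_b, filter)))
    }
    imgs <- as.matrix(Bt %*% vecs) * scale
    out[] <- imgs
    out
  }
}

# ---- total-variation denoiser ---------------------------------------------

tv_grad <- function(u) {
  gx <- cbind(u[, -1] - u[, -ncol(u)], 0)
  gy <- rbind(u[-1, ] - u[-nrow(u), ], 0)
  list(x = gx, y = gy)
}

tv_div <- function(px, py) {
  nr <- nrow(px); nc <- ncol(px)
  dx <- px - cbind(0, px[, -nc])
  dx[, nc] <- -px[, nc - 1]
  dy <- py - rbind(0, py[-nr, ])
  dy[nr, ] <- -py[nr - 1, ]
  dx + dy
}

#' Total-variation denoising (Chambolle projection algorithm)
#'
#' Solves `argmin_u 0.5 * ||u - g||^2 + weight * TV(u)` with isotropic TV by
#' dual projection iterations; this is the regularization step of the FISTA
#' reconstructor and a usable standalone denoiser.
#'
#' @param g Noisy image matrix.
#' @param weight TV weight (larger = smoother).
#' @param n_iter Number of dual iterations (default 10).
#' @return Denoised matrix.
#' @export
tv_denoise <- function(g, weight, n_iter = 10) {
  if (weight <= 0) return(g)
  px <- matrix(0, nrow(g), ncol(g))
  py <- px
  tau <- 0.125
  for (i in seq_len(n_iter)) {
    u <- tv_div(px, py) - g / weight
    gr <- tv_grad(u)
    mag <- sqrt(gr$x^2 + gr$y^2)
    px <- (px + tau * gr$x) / (1 + tau * mag)
    py <- (py + tau * gr$y) / (1 + tau * mag)
  }
  g - weight * tv_div(px, py)
}

tv_value <- function(u) {
  gr <- tv_grad(u)
  sum(sqrt(gr$x^2 + gr$y^2))
}

# ---- FISTA -----------------------------------------------------------------

#' Reconstruction configuration
#'
#' @param mu Regularization weight balancing data fidelity and the
#'   denoiser-based regularizer (>= 0).
#' @param max_iters Maximum FISTA iterations.
#' @param rel_tol Relative-change stopping tolerance.
#' @param denoiser `"tv"` (Chambolle total variation, the default), `"none"`,
#'   or a function `(img, weight) -> img` plugged in as the proximal /
#'   regularization-by-denoising step (e.g. an external BM3D binding).
#' @param tv_iters Inner Chambolle iterations per proximal step.
#' @param nonneg Project each iterate onto nonnegative images (photon counts
#'   cannot be negative).
#' @param power_iters Power iterations used to estimate the Lipschitz
#'   constant of the gradient (largest eigenvalue of `F' F`).
#' @param safety Multiplicative safety factor on the Lipschitz estimate.
#' @return A list of class `lift_recon_config`.
#' @export
recon_config <- function(mu = 0.05, max_iters = 100, rel_tol = 1e-5,
                         denoiser = "tv", tv_iters = 10, nonneg = TRUE,
                         power_iters = 20, safety = 1.05) {
  stopifnot(mu >= 0, max_iters >= 1, rel_tol > 0)
  if (!is.function(denoiser)) denoiser <- match.arg(denoiser, c("tv", "none"))
  structure(list(mu = mu, max_iters = max_iters, rel_tol = rel_tol,
                 denoiser = denoiser, tv_iters = tv_iters, nonneg = nonneg,
                 power_iters = power_iters, safety = safety),
            class = "lift_recon_config")
}

# largest eigenvalue of t(A) %*% A by power iteration (deterministic start)
operator_lipschitz <- function(A, n_iter = 20, safety = 1.05) {
  n <- ncol(A)
  v <- rep(1, n) + sin(seq_len(n))   # deterministic, not axis-aligned
  v <- v / sqrt(sum(v^2))
  lam <- 1
  for (i in seq_len(n_iter)) {
    w <- as.vector(Matrix::crossprod(A, A %*% v))
    lam <- sqrt(sum(w^2))
    v <- w / lam
  }
  lam * safety
}

#' FISTA reconstruction with denoiser regularization
#'
#' Solves `argmin_h ||f - F(d) h||_2^2 + mu * phi(h)` by the fast iterative
#' shrinkage-thresholding algorithm with momentum, a Lipschitz step size from
#' power iteration on `F'F`, the regularizer applied as a denoising proximal
#' step (Chambolle TV by default), nonnegativity projection, and a monotone
#' safeguard so the objective trace is non-increasing after the first
#' iterate. With `mu = 0` it reduces to projected-gradient least squares.
#'
#' @param f A `lift_sinogram` (static, i.e. 2-D rows).
#' @param s Shear parameter of the reconstruction plane; the forward operator
#'   is built at this shear, so no prior refocusing is needed.
#' @param config A [recon_config()].
#' @param sysmat Optional precomputed `lift_system_matrix(geom, s)`.
#' @return `N x N` image matrix with attributes `objective` (trace),
#'   `converged`, `iterations`, `lipschitz`.
#' @export
fista_reconstruct <- function(f, s = 0, config = recon_config(),
                              sysmat = NULL) {
  stopifnot(inherits(f, "lift_sinogram"), inherits(config, "lift_recon_config"))
  if (length(dim(f$rows)) != 2) {
    stop("fista_reconstruct expects a static sinogram; reconstruct ",
         "time/spectral stacks per bin (see fbp_reconstruct or vapply)",
         call. = FALSE)
  }
  geom <- f$geom
  N <- geom$N
  A <- sysmat %||% lift_system_matrix(geom, s)
  y <- as.vector(t(f$rows))
  L <- operator_lipschitz(A, config$power_iters, config$safety)
  denoise <- switch(
    class(config$denoiser)[1],
    "function" = config$denoiser,
    if (config$denoiser == "tv") {
      function(img, w) tv_denoise(img, w, config$tv_iters)
    } else {
      function(img, w) img
    }
  )
  reg_value <- if (is.character(config$denoiser) && config$denoiser == "tv") {
    tv_value
  } else {
    function(u) 0
  }
  objective <- function(xv) {
    r <- y - as.vector(A %*% xv)
    0.5 * sum(r^2) + config$mu * reg_value(matrix(xv, N, N))
  }
  x_cur <- rep(0, N * N)
  z <- x_cur
  t_cur <- 1
  obj <- numeric(0)
  obj_cur <- objective(x_cur)
  cand_prev <- x_cur
  converged <- FALSE
  for (it in seq_len(config$max_iters)) {
    grad <- as.vector(Matrix::crossprod(A, A %*% z - y))
    cand <- matrix(z - grad / L, N, N)
    if (config$mu > 0) cand <- denoise(cand, config$mu / L)
    if (config$nonneg) cand[cand < 0] <- 0
    cand <- as.vector(cand)
    obj_cand <- objective(cand)
    # monotone safeguard: keep the better of candidate and current iterate
    if (obj_cand <= obj_cur) {
      x_new <- cand; obj_new <- obj_cand
    } else {
      x_new <- x_cur; obj_new <- obj_cur
    }
    t_next <- (1 + sqrt(1 + 4 * t_cur^2)) / 2
    z <- x_new + (t_cur / t_next) * (cand - x_new) +
      ((t_cur - 1) / t_next) * (x_new - x_cur)
    rel <- sqrt(sum((cand - cand_prev)^2)) / max(sqrt(sum(cand^2)), 1e-12)
    cand_prev <- cand
    x_cur <- x_new
    obj_cur <- obj_new
    t_cur <- t_next
    obj <- c(obj, obj_cur)
    if (it > 1 && rel < config$rel_tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged && config$max_iters > 1) {
    warning("FISTA did not reach rel_tol in ", config$max_iters,
            " iterations; returning best iterate", call. = FALSE)
  }
  img <- matrix(x_cur, N, N)
  attr(img, "objective") <- obj
  attr(img, "converged") <- converged
  attr(img, "iterations") <- length(obj)
  attr(img, "lipschitz") <- L
  img
}
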