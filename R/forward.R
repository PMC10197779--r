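#' @importFrom rlang .data
#' @importFrom stats lm coef fft mvfft rpois rnorm runif sd quantile approx setNames
#' @importFrom utils head tail
NULL

# ---- low-level resampling -------------------------------------------------
#
# All image operators share one affine inverse-mapping bilinear resampler.
# Conventions: img[row, col], 0-based pixel coordinates x = col - 1 (right),
# y = row - 1 (down), grid centre at ((N-1)/2, (N-1)/2). Rotation by theta is
# counter-clockwise as displayed (row index increasing downward). Content
# translation by (dx, dy) moves features +dx columns and +dy rows, and is
# applied *before* the rotation, matching the acquisition chain
# shear -> dove-prism rotation -> cylindrical-lens projection.
# Out-of-bounds samples are zero.
affine_resample <- function(img, theta_deg = 0, dx = 0, dy = 0) {
  stopifnot(is.matrix(img))
  nr <- nrow(img); nc <- ncol(img)
  th <- (theta_deg %% 360) * pi / 180
  ct <- cos(th); st <- sin(th)
  cx <- (nc - 1) / 2; cy <- (nr - 1) / 2
  x <- rep(0:(nc - 1), each = nr) - cx   # column-major traversal
  y <- rep(0:(nr - 1), times = nc) - cy
  # inverse rotation (display-CCW forward => inverse uses -theta), then
  # undo the pre-rotation translation
  sx <- ct * x - st * y + cx - dx
  sy <- st * x + ct * y + cy - dy
  bilinear_gather(img, sx, sy, nr, nc)
}

bilinear_gather <- function(img, sx, sy, nr, nc) {
  ix <- floor(sx); iy <- floor(sy)
  fx <- sx - ix; fy <- sy - iy
  out <- numeric(length(sx))
  for (corner in 1:4) {
    ox <- if (corner %in% c(2, 4)) 1 else 0
    oy <- if (corner %in% c(3, 4)) 1 else 0
    px <- ix + ox; py <- iy + oy
    w <- (if (ox == 1) fx else 1 - fx) * (if (oy == 1) fy else 1 - fy)
    ok <- px >= 0 & px < nc & py >= 0 & py < nr & w > 0
    if (any(ok)) {
      idx <- py[ok] + 1L + px[ok] * nr
      out[ok] <- out[ok] + w[ok] * img[idx]
    }
  }
  matrix(out, nrow = nr, ncol = nc)
}

# ---- elementary operators -------------------------------------------------

#' Rotate an image about its centre
#'
#' Emulates the dove prism: a prism rotated by `theta/2` rotates the image by
#' `theta`. Rotation sense is counter-clockwise as displayed with the row
#' index increasing downward; bilinear interpolation with zero padding;
#' pixel centre convention `((N-1)/2, (N-1)/2)`.
#'
#' @param img Numeric matrix.
#' @param theta_deg Rotation angle in degrees (any real; reduced mod 360).
#' @return Rotated matrix of the same size.
#' @export
rotate_image <- function(img, theta_deg) {
  if ((theta_deg %% 360) == 0) return(img)
  affine_resample(img, theta_deg = theta_deg)
}

#' En-face projection of a perspective image
#'
#' Collapses an image into a 1-D profile by summing over rows (the optical
#' cylindrical lens integrating along the y-axis), so the projection is
#' indexed by image column. Total intensity is conserved.
#'
#' @param img Numeric matrix.
#' @return Numeric vector of length `ncol(img)`.
#' @export
project_enface <- function(img) {
  stopifnot(is.matrix(img))
  colSums(img)
}

#' Shear-induced shift of a 1-D sub-aperture projection
#'
#' For sub-aperture `(u, v)` at projection angle `theta`, the depth-dependent
#' shear displaces the 1-D projection by `s*u*sin(theta) - s*v*cos(theta)`
#' pixels along the projection axis.
#'
#' @param s Shear parameter (pixels per unit aperture coordinate).
#' @param u,v Normalized aperture coordinates of the view.
#' @param theta_deg Projection angle, degrees.
#' @return Signed shift in pixels.
#' @export
shear_shift <- function(s, u, v, theta_deg) {
  th <- theta_deg * pi / 180
  s * u * sin(th) - s * v * cos(th)
}

# Shift actually seen on the detector axis under this package's conventions:
# the prism angle is measured from the projection (y) axis, so the
# detector-frame displacement is shear_shift evaluated at theta + 90 degrees,
# i.e. s * (u*cos(theta) + v*sin(theta)). Both forward projection and
# refocusing use this single definition, which is what makes refocusing
# exactly undo the acquisition shear.
projection_shift <- function(s, u, v, theta_deg) {
  shear_shift(s, u, v, theta_deg + 90)
}

#' Render the perspective image of a feature kernel as seen from a view
#'
#' Applies the depth-dependent disparity: the common feature kernel `h` is
#' translated by `(s*u, s*v)` pixels (positive `u` toward increasing column,
#' positive `v` toward increasing row), with bilinear interpolation and
#' zero-filled borders.
#'
#' @param h Feature kernel, numeric matrix (nonnegative photon counts).
#' @param view Length-2 numeric `(u, v)` aperture coordinates.
#' @param s Shear parameter in pixels.
#' @return Matrix of the same size as `h`.
#' @export
render_perspective <- function(h, view, s) {
  stopifnot(is.matrix(h), length(view) == 2)
  if (s == 0) return(h)
  affine_resample(h, theta_deg = 0, dx = s * view[1], dy = s * view[2])
}

# ---- sparse forward operator ---------------------------------------------

# Sparse bilinear interpolation matrix W (N^2 x N^2, column-major vec) for
# out(p) = in(R_{-theta}(p - c) + c - t); at most 4 nonzeros per row.
affine_matrix <- function(N, theta_deg, dx = 0, dy = 0) {
  th <- (theta_deg %% 360) * pi / 180
  ct <- cos(th); st <- sin(th)
  cx <- (N - 1) / 2
  x <- rep(0:(N - 1), each = N) - cx
  y <- rep(0:(N - 1), times = N) - cx
  sx <- ct * x - st * y + cx - dx
  sy <- st * x + ct * y + cx - dy
  ix <- floor(sx); iy <- floor(sy)
  fx <- sx - ix; fy <- sy - iy
  n2 <- N * N
  rows <- integer(0); cols <- integer(0); vals <- numeric(0)
  p <- seq_len(n2)
  for (corner in 1:4) {
    ox <- if (corner %in% c(2, 4)) 1 else 0
    oy <- if (corner %in% c(3, 4)) 1 else 0
    px <- ix + ox; py <- iy + oy
    w <- (if (ox == 1) fx else 1 - fx) * (if (oy == 1) fy else 1 - fy)
    ok <- px >= 0 & px < N & py >= 0 & py < N & w > 1e-12
    if (any(ok)) {
      rows <- c(rows, p[ok])
      cols <- c(cols, py[ok] + 1L + px[ok] * N)
      vals <- c(vals, w[ok])
    }
  }
  Matrix::sparseMatrix(i = rows, j = cols, x = vals, dims = c(n2, n2))
}

# N x N^2 en-face projection matrix: row j sums image column j.
projection_matrix <- function(N) {
  j <- rep(seq_len(N), each = N)            # projection bin = image column
  p <- seq_len(N * N)                       # column-major vec index
  Matrix::sparseMatrix(i = j, j = p, x = 1, dims = c(N, N * N))
}

#' Sparse system matrix of the forward model
#'
#' Assembles the depth-dependent forward operator `F(d)` as an explicit
#' sparse matrix mapping a vectorized `N x N` feature kernel to the stacked
#' sinogram rows of the geometry's angle plan. Row block `r` applies
#' shear translation (view `k`, shear `s`), rotation by the row's angle and
#' en-face projection, discretized by distributing each voxel's photons onto
#' the detector with a bilinear footprint (the adjoint of inverse-mapping
#' interpolation). This splat discretization conserves photon mass exactly
#' for in-field content, and its exact transpose is the adjoint used by
#' back-projection and iterative reconstruction.
#'
#' @param geom A [lift_geometry()].
#' @param s Shear parameter (pixels); 0 reconstructs the nominal focal plane.
#' @return A `dgCMatrix` of dimension `(nrow(angle_plan(geom)) * N) x N^2`.
#'   Rows are ordered row-major per sinogram row: entries
#'   `(r-1)*N + 1 .. r*N` hold projection row `r`.
#' @export
lift_system_matrix <- function(geom, s = 0) {
  stopifnot(inherits(geom, "lift_geometry"))
  N <- geom$N
  plan <- geom$plan
  R <- nrow(plan)
  cx <- (N - 1) / 2
  x0 <- rep(0:(N - 1), each = N) - cx   # column-major source coordinates
  y0 <- rep(0:(N - 1), times = N) - cx
  n2 <- N * N
  p_src <- seq_len(n2)
  ii <- vector("list", R); jj <- vector("list", R); vv <- vector("list", R)
  for (r in seq_len(R)) {
    th <- plan$angle_deg[r] * pi / 180
    ct <- cos(th); st <- sin(th)
    tx <- s * plan$u[r]; ty <- s * plan$v[r]
    # a voxel at p lands at R_theta(p + t - c) + c (display-CCW rotation);
    # the en-face row sum collapses the y bilinear footprint to the fraction
    # of it that stays in-field, leaving a 1-D footprint on the detector axis
    xl <- ct * (x0 + tx) + st * (y0 + ty) + cx
    yl <- -st * (x0 + tx) + ct * (y0 + ty) + cx
    ix <- floor(xl); fx <- xl - ix
    iy <- floor(yl); fy <- yl - iy
    yfac <- (iy >= 0 & iy <= N - 1) * (1 - fy) + (iy + 1 >= 0 & iy + 1 <= N - 1) * fy
    base <- (r - 1L) * N
    w1 <- (1 - fx) * yfac
    w2 <- fx * yfac
    ok1 <- ix >= 0 & ix <= N - 1 & w1 > 1e-12
    ok2 <- ix + 1 >= 0 & ix + 1 <= N - 1 & w2 > 1e-12
    ii[[r]] <- c(base + ix[ok1] + 1L, base + ix[ok2] + 2L)
    jj[[r]] <- c(p_src[ok1], p_src[ok2])
    vv[[r]] <- c(w1[ok1], w2[ok2])
  }
  Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(vv),
                       dims = c(R * N, n2))
}

# ---- sinogram container ---------------------------------------------------

new_sinogram <- function(rows, geom, time_axis = NULL, wavelength_axis = NULL,
                         meta = list()) {
  structure(
    list(rows = rows, plan = geom$plan, geom = geom,
         time_axis = time_axis, wavelength_axis = wavelength_axis,
         meta = meta),
    class = "lift_sinogram"
  )
}

#' @export
print.lift_sinogram <- function(x, ...) {
  d <- dim(x$rows)
  cat("<lift_sinogram>", d[1], "rows x", d[2], "detector pixels")
  if (length(d) > 2) cat(" x", paste(d[-(1:2)], collapse = " x "), "bins")
  cat("\n  views:", x$geom$K, " angles:", x$geom$Ntheta,
      " CR:", signif(x$geom$N / x$geom$Ntheta, 4), "\n")
  invisible(x)
}

#' Tidy a sinogram into a long tibble
#'
#' @param x A `lift_sinogram`.
#' @param ... Unused.
#' @return Tibble with columns `row`, `view`, `angle_deg`, `pixel`, `value`
#'   (static sinograms only; time/spectral stacks add `time_ns` /
#'   `wavelength_nm`).
#' @export
tidy.lift_sinogram <- function(x, ...) {
  d <- dim(x$rows)
  base <- x$plan |> dplyr::mutate(row = dplyr::row_number())
  if (length(d) == 2) {
    tidyr::expand_grid(row = seq_len(d[1]), pixel = seq_len(d[2])) |>
      dplyr::mutate(value = as.vector(t(x$rows))) |>
      dplyr::left_join(base, by = "row") |>
      dplyr::select("row", "view", "angle_deg", "pixel", "value")
  } else {
    stop("tidy() supports static sinograms; index time/spectral stacks first",
         call. = FALSE)
  }
}

# ---- forward projection ---------------------------------------------------

#' Forward-project a scene into a sinogram
#'
#' Applies the full acquisition model: for every sinogram row (view `k`,
#' angle `theta`) the scene plane at depth `d` is sheared by
#' `(s(d)*u_k, s(d)*v_k)`, rotated by `theta` and collapsed into a 1-D
#' en-face projection; depth planes add incoherently. Time-resolved (and
#' spectrally resolved) scenes are projected independently per bin with the
#' same operator, so the result is a stack of sinograms indexed by time
#' (and wavelength). The operator is linear in the scene.
#'
#' @param scene One of: an `N x N` matrix (single plane), a 3-D array
#'   `N x N x Z` of depth planes, or a [lift_scene()] (which may carry time
#'   and wavelength axes).
#' @param geom A [lift_geometry()] with matching `N`.
#' @param depths_um Depths of the scene planes (micron); default 0 for a
#'   matrix, taken from the scene object otherwise. Mapped to shear via
#'   [depth_to_shear()].
#' @return A `lift_sinogram`; `$rows` is `(sum n_k) x N` for a static scene,
#'   with trailing time/wavelength dimensions for resolved scenes.
#' @export
forward_sinogram <- function(scene, geom, depths_um = NULL) {
  stopifnot(inherits(geom, "lift_geometry"))
  N <- geom$N
  if (inherits(scene, "lift_scene")) {
    vox <- scene$voxels
    if (is.null(depths_um)) depths_um <- scene$depths_um
    time_axis <- scene$time_axis_ns
    wavelength_axis <- scene$wavelength_axis_nm
  } else if (is.matrix(scene)) {
    vox <- array(scene, dim = c(dim(scene), 1L))
    if (is.null(depths_um)) depths_um <- 0
    time_axis <- NULL; wavelength_axis <- NULL
  } else if (is.array(scene)) {
    vox <- scene
    if (is.null(depths_um)) depths_um <- rep(0, dim(scene)[3])
    time_axis <- NULL; wavelength_axis <- NULL
  } else {
    stop("scene must be a matrix, array or lift_scene", call. = FALSE)
  }
  dm <- dim(vox)
  if (dm[1] != N || dm[2] != N) {
    stop("scene size ", dm[1], "x", dm[2], " does not match geometry N = ", N,
         call. = FALSE)
  }
  nz <- dm[3]
  if (length(depths_um) != nz) {
    stop("need one depth per scene plane", call. = FALSE)
  }
  nbin <- if (length(dm) > 3) prod(dm[-(1:3)]) else 1L
  R <- nrow(geom$plan)
  acc <- matrix(0, R * N, nbin)
  for (z in seq_len(nz)) {
    s <- depth_to_shear(geom, depths_um[z])
    A <- lift_system_matrix(geom, s)
    H <- matrix(vox[slice.index(vox, 3) == z], nrow = N * N, ncol = nbin)
    acc <- acc + as.matrix(A %*% H)
  }
  if (nbin == 1L) {
    rows <- t(matrix(acc[, 1], nrow = N))     # R x N
  } else {
    rows <- array(0, dim = c(R, N, dm[-(1:3)]))
    for (b in seq_len(nbin)) {
      idx <- slice_index_flat(dim(rows), b, R * N)
      rows[idx] <- as.vector(t(matrix(acc[, b], nrow = N)))
    }
  }
  new_sinogram(rows, geom,
               time_axis = time_axis, wavelength_axis = wavelength_axis,
               meta = list(depths_um = depths_um))
}

# flat indices of the b-th trailing slice of an array whose leading block
# has `lead` elements
slice_index_flat <- function(dm, b, lead) {
  (b - 1L) * lead + seq_len(lead)
}
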