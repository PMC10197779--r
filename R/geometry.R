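#' Acquisition geometry for light-field tomographic FLIM
#'
#' A `lift_geometry` describes how a scene is measured: the image is `N`
#' pixels per side, the objective pupil is divided into `K` sub-apertures
#' (views) at normalized coordinates `(u, v)` inside the unit pupil, and a
#' plan of `Ntheta` projection orientations in `[0, 180)` degrees is
#' partitioned over the views, so that view `k` contributes `n_k` rows to the
#' sinogram. Non-compressive acquisition uses `Ntheta = N`; `Ntheta < N`
#' is compressive with compression ratio `CR = N / Ntheta`.
#'
#' Conventions (used consistently by the forward and inverse operators):
#' images are `N x N` matrices indexed `[row, col]` with the grid centre at
#' `((N-1)/2, (N-1)/2)` in 0-based pixel units; rotation is counter-clockwise
#' as displayed with the row index increasing downward; the en-face
#' projection sums over rows so a projection row is indexed by image column.
#'
#' @param N Integer, image size in pixels per side (N >= 2).
#' @param K Integer, number of views (sub-apertures), `1 <= K <= Ntheta`.
#' @param Ntheta Integer, total number of projection angles. Defaults to `N`
#'   (non-compressive).
#' @param apertures Optional two-column matrix or data frame of normalized
#'   aperture coordinates `(u, v)` in `[-1, 1]^2`, one row per view. Default:
#'   `K` points evenly spaced on a ring of radius 0.8 in the unit pupil.
#' @param scheme Angle-partition scheme: `"balanced"` (default; evenly spaced
#'   angles dealt round-robin over views so every view sees a spread of
#'   orientations and `|n_k - Ntheta/K| <= 1`) or `"custom"`, in which case
#'   `permutation` gives the view assignment.
#' @param permutation For `scheme = "custom"`: integer vector of length
#'   `Ntheta` with values in `1..K`, assigning each angle to a view.
#' @param pixel_pitch_um Physical pixel pitch at the sample (micron/pixel).
#' @param shear_per_um Shear parameter accrued per micron of defocus
#'   (pixels/micron); with `shear_offset` it defines the default linear
#'   depth-to-shear calibration `s(d) = shear_per_um * d + shear_offset`.
#' @param shear_offset Shear at depth zero (pixels), normally 0.
#'
#' @return An object of class `lift_geometry` with the angle plan as a tibble
#'   (`view`, `angle_deg`, `u`, `v`) in sinogram row order.
#' @examples
#' g <- lift_geometry(N = 64, K = 5, Ntheta = 32)
#' angle_plan(g)
#' @export
lift_geometry <- function(N, K, Ntheta = N, apertures = NULL,
                          scheme = c("balanced", "custom"),
                          permutation = NULL,
                          pixel_pitch_um = 0.9,
                          shear_per_um = 0.5,
                          shear_offset = 0) {
  scheme <- match.arg(scheme)
  N <- as.integer(N); K <- as.integer(K); Ntheta <- as.integer(Ntheta)
  if (N < 2L) stop("image size N must be at least 2", call. = FALSE)
  if (K < 1L) stop("need at least one view", call. = FALSE)
  if (K > Ntheta) {
    stop("invalid view plan: K (", K, ") exceeds Ntheta (", Ntheta, ")",
         call. = FALSE)
  }
  if (is.null(apertures)) {
    apertures <- default_apertures(K)
  } else {
    apertures <- as.matrix(apertures)
    if (nrow(apertures) != K || ncol(apertures) != 2) {
      stop("apertures must be a K x 2 matrix of (u, v)", call. = FALSE)
    }
    if (any(abs(apertures) > 1)) {
      stop("aperture coordinates must lie in [-1, 1]^2", call. = FALSE)
    }
  }
  plan <- build_view_plan(K, Ntheta, scheme, permutation)
  plan$u <- apertures[plan$view, 1]
  plan$v <- apertures[plan$view, 2]
  structure(
    list(
      N = N, K = K, Ntheta = Ntheta,
      apertures = apertures,
      plan = plan,
      pixel_pitch_um = pixel_pitch_um,
      shear_per_um = shear_per_um,
      shear_offset = shear_offset
    ),
    class = "lift_geometry"
  )
}

#' Partition evenly spaced projection angles over views
#'
#' Generates `Ntheta` angles evenly spaced in `[0, 180)` degrees (the dove
#' prism physically spans 0-90 degrees and doubles to image rotation) and
#' assigns each to exactly one view. The balanced scheme deals angles
#' round-robin so each view receives `floor(Ntheta/K)` or `ceiling(Ntheta/K)`
#' angles spread across the full angular range; the custom scheme applies a
#' caller-supplied assignment (the hook for engineered off-focus PSFs).
#'
#' @inheritParams lift_geometry
#' @return Tibble with columns `view` and `angle_deg`, in sinogram row order
#'   (all rows of view 1, then view 2, ...; angles increasing within a view).
#' @export
build_view_plan <- function(K, Ntheta, scheme = c("balanced", "custom"),
                            permutation = NULL) {
  scheme <- match.arg(scheme)
  K <- as.integer(K); Ntheta <- as.integer(Ntheta)
  if (K < 1L || Ntheta < 1L || K > Ntheta) {
    stop("invalid view plan: need 1 <= K <= Ntheta", call. = FALSE)
  }
  angles <- (seq_len(Ntheta) - 1L) * 180 / Ntheta
  if (scheme == "balanced") {
    assignment <- rep_len(seq_len(K), Ntheta)
  } else {
    if (is.null(permutation) || length(permutation) != Ntheta ||
        !all(permutation %in% seq_len(K))) {
      stop("custom scheme needs a length-Ntheta assignment with values in 1..K",
           call. = FALSE)
    }
    assignment <- as.integer(permutation)
    if (!all(seq_len(K) %in% assignment)) {
      stop("custom assignment must use every view at least once", call. = FALSE)
    }
  }
  tibble::tibble(view = assignment, angle_deg = angles) |>
    dplyr::arrange(.data$view, .data$angle_deg)
}

# K sub-apertures evenly spaced on a ring of radius 0.8 in the unit pupil
# (single view sits on the axis). The ring keeps (u, v) well spread so
# view-dependent disparity samples many directions.
default_apertures <- function(K) {
  if (K == 1L) return(matrix(0, 1, 2, dimnames = list(NULL, c("u", "v"))))
  ang <- 2 * pi * (seq_len(K) - 1L) / K
  cbind(u = 0.8 * cos(ang), v = 0.8 * sin(ang))
}

#' @export
print.lift_geometry <- function(x, ...) {
  nk <- table(x$plan$view)
  cat("<lift_geometry> N =", x$N, " K =", x$K, " Ntheta =", x$Ntheta,
      " CR =", signif(x$N / x$Ntheta, 4), "\n")
  cat("  rows per view n_k:", paste(as.integer(nk), collapse = " "), "\n")
  cat("  depth-to-shear: s(d) =", x$shear_per_um, "* d +", x$shear_offset,
      " (pixels, d in um)\n")
  invisible(x)
}

#' Angle plan of a geometry
#'
#' @param geom A [lift_geometry()].
#' @return Tibble with one row per sinogram row: `view`, `angle_deg`, `u`, `v`.
#' @export
angle_plan <- function(geom) {
  stopifnot(inherits(geom, "lift_geometry"))
  geom$plan
}

#' Depth-to-shear mapping of a geometry
#'
#' Applies the geometry's linear depth calibration `s(d)`.
#'
#' @param geom A [lift_geometry()].
#' @param depth_um Depth(s) relative to nominal focus, micron.
#' @return Shear parameter(s), pixels.
#' @export
depth_to_shear <- function(geom, depth_um) {
  stopifnot(inherits(geom, "lift_geometry"))
  geom$shear_per_um * depth_um + geom$shear_offset
}
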