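# ---- focus measure ---------------------------------------------------------

#' Sum-of-modified-Laplacian focus measure
#'
#' Per-pixel focus map: the modified Laplacian `|2u - u_left - u_right| +
#' |2u - u_up - u_down|` summed over a `w x w` window. Large values mark
#' sharp (in-focus) structure; a constant image maps to zero everywhere and
#' blurring strictly reduces the measure on textured content.
#'
#' @param img Image matrix.
#' @param window Odd window size `w` (default 5).
#' @return Nonnegative matrix of the same size.
#' @export
focus_measure <- function(img, window = 5) {
  stopifnot(is.matrix(img), window %% 2 == 1)
  nr <- nrow(img); nc <- ncol(img)
  pad <- function(m) m[c(1, seq_len(nr), nr), c(1, seq_len(nc), nc)]
  p <- pad(img)
  i <- 1 + seq_len(nr); j <- 1 + seq_len(nc)
  ml <- abs(2 * p[i, j] - p[i, j - 1] - p[i, j + 1]) +
    abs(2 * p[i, j] - p[i - 1, j] - p[i + 1, j])
  box <- rep(1, window)
  half <- (window - 1) / 2
  ext <- function(n) c(rep(1, half), seq_len(n), rep(n, half))
  mlp <- ml[ext(nr), ext(nc)]
  sm <- apply(mlp, 2, function(col) stats::filter(col, box, sides = 2))
  sm <- t(apply(sm, 1, function(row) stats::filter(row, box, sides = 2)))
  sm[half + seq_len(nr), half + seq_len(nc)]
}

# ---- depth sweep and extended depth of field -------------------------------

#' Reconstruct a sinogram over a sweep of depths
#'
#' Refocuses and reconstructs the measurement at each depth in `depths_um`
#' (via the geometry's depth-to-shear calibration), producing a depth stack
#' with per-pixel focus maps.
#'
#' @param f A static `lift_sinogram`.
#' @param depths_um Strictly increasing depths, micron (non-empty).
#' @param method `"fbp"` (default) or `"fista"`.
#' @param config [recon_config()] for the FISTA method.
#' @param window Focus-measure window.
#' @return Object of class `lift_depth_stack`: list with `images` (list of
#'   N x N matrices), `depths_um`, `focus` (list of focus maps).
#' @export
depth_sweep <- function(f, depths_um, method = c("fbp", "fista"),
                        config = recon_config(), window = 5) {
  stopifnot(inherits(f, "lift_sinogram"), length(depths_um) >= 1)
  if (is.unsorted(depths_um, strictly = TRUE) && length(depths_um) > 1) {
    stop("depths must be strictly increasing", call. = FALSE)
  }
  method <- match.arg(method)
  geom <- f$geom
  A0 <- if (method == "fbp") lift_system_matrix(geom, 0) else NULL
  images <- lapply(depths_um, function(d) {
    s <- depth_to_shear(geom, d)
    if (method == "fbp") {
      fbp_reconstruct(f, s = s, sysmat = A0)
    } else {
      suppressWarnings(
        fista_reconstruct(f, s = s, config = config,
                          sysmat = lift_system_matrix(geom, s)))
    }
  })
  focus <- lapply(images, focus_measure, window = window)
  structure(list(images = images, depths_um = depths_um, focus = focus,
                 geom = geom, method = method),
            class = "lift_depth_stack")
}

#' @export
print.lift_depth_stack <- function(x, ...) {
  cat("<lift_depth_stack>", length(x$images), "planes,",
      paste(range(x$depths_um), collapse = " to "), "um (", x$method, ")\n")
  invisible(x)
}

#' Assemble an all-in-focus (extended depth of field) image
#'
#' For each pixel, selects the depth plane maximizing the focus measure and
#' takes the reconstructed value there; exact focus ties go to the smallest
#' depth index.
#'
#' @param stack A [depth_sweep()] result.
#' @return List with `edof` (image matrix) and `depth_map` (matrix of
#'   argmax depths, micron).
#' @export
all_in_focus <- function(stack) {
  stopifnot(inherits(stack, "lift_depth_stack"))
  nz <- length(stack$images)
  N1 <- nrow(stack$images[[1]]); N2 <- ncol(stack$images[[1]])
  fcube <- array(unlist(stack$focus), c(N1, N2, nz))
  icube <- array(unlist(stack$images), c(N1, N2, nz))
  best <- apply(fcube, c(1, 2), which.max)   # first max wins ties
  pick <- cbind(rep(seq_len(N1), N2), rep(seq_len(N2), each = N1),
                as.vector(best))
  edof <- matrix(icube[pick], N1, N2)
  depth_map <- matrix(stack$depths_um[as.vector(best)], N1, N2)
  list(edof = edof, depth_map = depth_map)
}

# ---- depth calibration -----------------------------------------------------

#' Fit the linear depth-to-shear calibration
#'
#' Least-squares line through (depth, best-focus shear) pairs, as measured by
#' sweeping the shear parameter for a bead translated through known physical
#' depths.
#'
#' @param pairs Data frame with columns `depth_um` and `shear` (>= 2 distinct
#'   depths).
#' @return Object of class `lift_shear_cal`: the underlying `lm` fit plus
#'   `slope` (pixels/micron), `intercept` (pixels), `valid_range`.
#' @export
calibrate_depth <- function(pairs) {
  pairs <- tibble::as_tibble(pairs)
  if (!all(c("depth_um", "shear") %in% names(pairs))) {
    stop("pairs needs columns depth_um and shear", call. = FALSE)
  }
  if (length(unique(pairs$depth_um)) < 2) {
    stop("calibration error: need at least 2 distinct depths", call. = FALSE)
  }
  fit <- stats::lm(shear ~ depth_um, data = pairs)
  structure(list(fit = fit,
                 slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 valid_range = range(pairs$depth_um),
                 n = nrow(pairs)),
            class = "lift_shear_cal")
}

#' @export
print.lift_shear_cal <- function(x, ...) {
  cat("<lift_shear_cal> s(d) =", signif(x$slope, 6), "* d +",
      signif(x$intercept, 6), "\n  valid for d in [",
      paste(x$valid_range, collapse = ", "), "] um,", x$n, "points\n")
  invisible(x)
}

#' @export
tidy.lift_shear_cal <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble::tibble(term = c("intercept", "slope"),
                 estimate = s[, 1], std_error = s[, 2],
                 statistic = s[, 3], p_value = s[, 4])
}

#' @export
glance.lift_shear_cal <- function(x, ...) {
  s <- summary(x$fit)
  tibble::tibble(r_squared = s$r.squared, sigma = s$sigma, n = x$n,
                 slope = x$slope, intercept = x$intercept)
}

#' Map physical depth to shear with a fitted calibration
#'
#' @param cal A [calibrate_depth()] result.
#' @param depth_um Depths, micron.
#' @param warn Warn when extrapolating beyond the fitted range.
#' @return Shear parameter(s), pixels.
#' @export
shear_at_depth <- function(cal, depth_um, warn = TRUE) {
  stopifnot(inherits(cal, "lift_shear_cal"))
  if (warn && (any(depth_um < cal$valid_range[1]) ||
               any(depth_um > cal$valid_range[2]))) {
    warning("depth outside the calibrated range; extrapolating",
            call. = FALSE)
  }
  cal$slope * depth_um + cal$intercept
}
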