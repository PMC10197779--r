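# ---- compression ratio and scanning reduction ------------------------------

#' Compression ratio and scanning-reduction factors
#'
#' `CR = N / Ntheta`; against point scanning the acquisition reduces the
#' number of scan steps by `N * K` (the effective number of depth samples
#' equals the number of views K), and against line scanning by `K`.
#'
#' @param N Image pixels per side.
#' @param Ntheta Number of acquired projection angles.
#' @param K Number of views.
#' @return One-row tibble: `cr`, `point_scan_factor`, `line_scan_factor`.
#' @examples
#' compression_and_reduction(180, 180, 15)   # CR 1, factors 2700 and 15
#' @export
compression_and_reduction <- function(N, Ntheta, K) {
  stopifnot(N > 0, Ntheta > 0, K > 0)
  tibble::tibble(cr = N / Ntheta,
                 point_scan_factor = N * K,
                 line_scan_factor = K)
}

# ---- light throughput -------------------------------------------------------

#' System light throughput
#'
#' Direct (SPAD) mode: `zeta = p * kappa / (D0 * r)` — the sub-aperture
#' selection loss `D/D0` times the fraction of the projection line width
#' (`D * r`) covered by one detector pixel (`p * kappa`). Spectral mode:
#' `zeta = chi * eta / K` — sub-aperture loss `D/D0 = 1/K` times grating and
#' camera efficiencies; the pupil demagnification `r` plays no role there.
#'
#' @param mode `"flim"` (linear SPAD) or `"sflim"` (dispersed, gated camera).
#' @param pixel_pitch_p Detector pixel pitch (same length unit as `D0`).
#' @param fill_factor_kappa Detector fill factor in (0, 1].
#' @param full_aperture_D0 Objective aperture diameter.
#' @param pupil_demag_r Pupil demagnification ratio (> 0).
#' @param grating_efficiency_chi Grating diffraction efficiency in (0, 1].
#' @param quantum_efficiency_eta Camera quantum efficiency in (0, 1].
#' @param K Number of views.
#' @return Throughput `zeta` (dimensionless fraction).
#' @examples
#' throughput("sflim", grating_efficiency_chi = 0.75,
#'            quantum_efficiency_eta = 0.3, K = 15)   # 0.015
#' @export
throughput <- function(mode = c("flim", "sflim"),
                       pixel_pitch_p = NULL, fill_factor_kappa = NULL,
                       full_aperture_D0 = NULL, pupil_demag_r = NULL,
                       grating_efficiency_chi = NULL,
                       quantum_efficiency_eta = NULL, K = NULL) {
  mode <- match.arg(mode)
  if (mode == "flim") {
    if (is.null(pixel_pitch_p) || is.null(fill_factor_kappa) ||
        is.null(full_aperture_D0) || is.null(pupil_demag_r)) {
      stop("flim mode needs pixel_pitch_p, fill_factor_kappa, ",
           "full_aperture_D0 and pupil_demag_r", call. = FALSE)
    }
    stopifnot(pixel_pitch_p > 0, fill_factor_kappa > 0,
              fill_factor_kappa <= 1, full_aperture_D0 > 0, pupil_demag_r > 0)
    pixel_pitch_p * fill_factor_kappa / (full_aperture_D0 * pupil_demag_r)
  } else {
    if (is.null(grating_efficiency_chi) || is.null(quantum_efficiency_eta) ||
        is.null(K)) {
      stop("sflim mode needs grating_efficiency_chi, quantum_efficiency_eta ",
           "and K", call. = FALSE)
    }
    stopifnot(grating_efficiency_chi > 0, grating_efficiency_chi <= 1,
              quantum_efficiency_eta > 0, quantum_efficiency_eta <= 1, K >= 1)
    grating_efficiency_chi * quantum_efficiency_eta / K
  }
}

# ---- convolved-width deconvolution ------------------------------------------

#' Deconvolve a component width from a measured convolved width
#'
#' For discrete functions, the width of an m-fold convolution obeys
#' `w(f1 * ... * fm) = w(f1) + ... + w(fm) - (m - 1)`. Given the total
#' measured width and the known component widths, the remaining component is
#' `total - sum(known) + (m - 1)` where `m = length(known) + 1`.
#'
#' @param total_w Measured width of the convolution, pixels.
#' @param known_ws Widths of the known components, pixels.
#' @return One-row tibble: `width` (exact real value) and `width_px`
#'   (nearest integer pixel count).
#' @examples
#' deconvolved_width(5, 4)        # lateral resolution: 2 pixels
#' @export
deconvolved_width <- function(total_w, known_ws) {
  stopifnot(total_w > 0, length(known_ws) >= 1, all(known_ws > 0))
  m <- length(known_ws) + 1L
  w <- total_w - sum(known_ws) + (m - 1L)
  if (w < 0) {
    stop("infeasible width: components wider than the measured total",
         call. = FALSE)
  }
  tibble::tibble(width = w, width_px = round(w))
}

#' Width of a convolution of discrete components
#'
#' The composition rule inverse to [deconvolved_width()]:
#' `w = sum(widths) - (length(widths) - 1)`.
#'
#' @param widths Component widths, pixels.
#' @return Convolved width.
#' @examples
#' convolved_width(c(7, 7, 48))   # 60
#' @export
convolved_width <- function(widths) {
  stopifnot(length(widths) >= 1)
  sum(widths) - (length(widths) - 1L)
}

# ---- projection-centre calibration ------------------------------------------

#' Calibrate projection centres from a pinhole sinogram
#'
#' Localizes the centre `yp0(theta, k)` of each projection row of a pinhole
#' acquisition by an intensity-weighted centroid over a window around the
#' row maximum; the table aligns sinogram rows before reconstruction.
#'
#' @param f A `lift_sinogram` of a centred pinhole (each row must contain a
#'   single detectable peak).
#' @param window Half-width of the centroid window, pixels (default 5).
#' @param threshold Rows whose maximum is below `threshold * max(f)` raise a
#'   missing-signal error (default 1e-3).
#' @return Tibble of class `lift_center_cal`: `row`, `view`, `angle_deg`,
#'   `yp0` (0-based sub-pixel centre).
#' @export
calibrate_projection_center <- function(f, window = 5, threshold = 1e-3) {
  stopifnot(inherits(f, "lift_sinogram"), length(dim(f$rows)) == 2)
  gmax <- max(f$rows)
  if (gmax <= 0) stop("missing signal: sinogram is empty", call. = FALSE)
  N <- ncol(f$rows)
  yp0 <- vapply(seq_len(nrow(f$rows)), function(r) {
    v <- f$rows[r, ]
    if (max(v) < threshold * gmax) {
      stop("missing signal in sinogram row ", r, " (view ", f$plan$view[r],
           ", angle ", f$plan$angle_deg[r], ")", call. = FALSE)
    }
    pk <- which.max(v)
    sel <- max(1, pk - window):min(N, pk + window)
    sum((sel - 1) * v[sel]) / sum(v[sel])
  }, numeric(1))
  out <- f$plan |>
    dplyr::mutate(row = dplyr::row_number(), yp0 = yp0) |>
    dplyr::select("row", "view", "angle_deg", "yp0")
  class(out) <- c("lift_center_cal", class(out))
  out
}

# ---- spectral-axis calibration ----------------------------------------------

#' Fit the spectral axis (wavelength vs detector pixel)
#'
#' Least-squares line through (pixel, wavelength) calibration points from
#' monochromatic pinhole exposures; the slope is the spectral sampling of
#' the dispersed system (nm per pixel).
#'
#' @param pairs Data frame with columns `wavelength_nm` and `pixel` (>= 2
#'   distinct wavelengths).
#' @return Object of class `lift_spectral_cal` with `slope_nm_per_px`,
#'   `intercept_nm` and the underlying `lm` fit; has [tidy()] and
#'   [glance()] methods.
#' @export
fit_spectral_axis <- function(pairs) {
  pairs <- tibble::as_tibble(pairs)
  if (!all(c("wavelength_nm", "pixel") %in% names(pairs))) {
    stop("pairs needs columns wavelength_nm and pixel", call. = FALSE)
  }
  if (length(unique(pairs$wavelength_nm)) < 2) {
    stop("need at least 2 distinct wavelengths", call. = FALSE)
  }
  fit <- stats::lm(wavelength_nm ~ pixel, data = pairs)
  structure(list(fit = fit,
                 slope_nm_per_px = unname(coef(fit)[2]),
                 intercept_nm = unname(coef(fit)[1]),
                 n = nrow(pairs)),
            class = "lift_spectral_cal")
}

#' @export
print.lift_spectral_cal <- function(x, ...) {
  cat("<lift_spectral_cal> sampling =", signif(x$slope_nm_per_px, 4),
      "nm/pixel, intercept =", signif(x$intercept_nm, 6), "nm\n")
  invisible(x)
}

#' @export
tidy.lift_spectral_cal <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble::tibble(term = c("intercept_nm", "slope_nm_per_px"),
                 estimate = s[, 1], std_error = s[, 2],
                 statistic = s[, 3], p_value = s[, 4])
}

#' @export
glance.lift_spectral_cal <- function(x, ...) {
  s <- summary(x$fit)
  tibble::tibble(r_squared = s$r.squared, sigma = s$sigma, n = x$n,
                 slope_nm_per_px = x$slope_nm_per_px)
}
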