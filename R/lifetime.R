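# ---- TCSPC containers ------------------------------------------------------

#' Per-pixel TCSPC histogram set
#'
#' @param counts Integer matrix, pixels x time bins (nonnegative).
#' @param bin_width_ns Bin width, ns (default 0.05 = 50 ps).
#' @param time_zero Index convention: bin holding the laser reference after
#'   delay alignment (default 1).
#' @return Object of class `lift_tcspc`.
#' @export
tcspc_histograms <- function(counts, bin_width_ns = 0.05, time_zero = 1L) {
  counts <- as.matrix(counts)
  stopifnot(all(counts >= 0), bin_width_ns > 0)
  structure(list(counts = counts, bin_width_ns = bin_width_ns,
                 time_zero = as.integer(time_zero)),
            class = "lift_tcspc")
}

#' @export
print.lift_tcspc <- function(x, ...) {
  cat("<lift_tcspc>", nrow(x$counts), "pixels x", ncol(x$counts),
      "bins, dt =", x$bin_width_ns * 1000, "ps\n")
  invisible(x)
}

#' Time axis of a histogram set (bin centres, ns)
#' @param h A `lift_tcspc`.
#' @export
tcspc_time_axis <- function(h) {
  (seq_len(ncol(h$counts)) - 0.5) * h$bin_width_ns
}

#' SPAD correction tables
#'
#' @param background Per-pixel background histogram (same shape as the data)
#'   or `NULL`.
#' @param zero_ref_bins Integer per-pixel delay: the bin index registering
#'   the laser reference at each pixel, or `NULL` for no delay correction.
#' @param nonlin_matrix Per-pixel, per-bin multiplicative weights from the
#'   uniform-illumination equalization ([build_nonlinearity_correction()]),
#'   or `NULL`.
#' @return Object of class `lift_corrections`.
#' @export
correction_tables <- function(background = NULL, zero_ref_bins = NULL,
                              nonlin_matrix = NULL) {
  structure(list(background = background, zero_ref_bins = zero_ref_bins,
                 nonlin_matrix = nonlin_matrix),
            class = "lift_corrections")
}

# circular shift of a vector so that entry `ref` maps to index 1
circshift_to_zero <- function(v, ref) {
  n <- length(v)
  k <- (ref - 1L) %% n
  if (k == 0) v else c(v[(k + 1):n], v[1:k])
}

#' Post-process raw SPAD histograms
#'
#' Applies the three standard corrections in order: background subtraction
#' (clipped at zero — counts cannot be negative), delay correction (circular
#' shift per pixel so the zero-reference bin maps to bin 1; the histogram is
#' periodic in the laser period), and nonlinearity correction (per-bin
#' multiplication by the equalization weights, then rescaled so each pixel's
#' total count is preserved).
#'
#' @param h A [tcspc_histograms()].
#' @param corrections A [correction_tables()].
#' @return Corrected `lift_tcspc`.
#' @export
preprocess_histograms <- function(h, corrections) {
  stopifnot(inherits(h, "lift_tcspc"), inherits(corrections, "lift_corrections"))
  counts <- h$counts
  np <- nrow(counts); nb <- ncol(counts)
  bg <- corrections$background
  if (!is.null(bg)) {
    bg <- as.matrix(bg)
    if (!all(dim(bg) == dim(counts))) {
      stop("background shape does not match histograms", call. = FALSE)
    }
    counts <- pmax(counts - bg, 0)
  }
  zr <- corrections$zero_ref_bins
  if (!is.null(zr)) {
    if (length(zr) == 1L) zr <- rep(zr, np)
    if (length(zr) != np) stop("need one zero-reference bin per pixel",
                               call. = FALSE)
    for (p in seq_len(np)) counts[p, ] <- circshift_to_zero(counts[p, ], zr[p])
  }
  nl <- corrections$nonlin_matrix
  if (!is.null(nl)) {
    nl <- as.matrix(nl)
    if (!all(dim(nl) == dim(counts))) {
      stop("nonlinearity matrix shape does not match histograms",
           call. = FALSE)
    }
    tot0 <- rowSums(counts)
    counts <- counts * nl
    tot1 <- rowSums(counts)
    rescale <- ifelse(tot1 > 0, tot0 / tot1, 1)
    counts <- counts * rescale
  }
  tcspc_histograms(counts, h$bin_width_ns, h$time_zero)
}

#' Build the SPAD nonlinearity (differential-gain) correction
#'
#' Averages repeated histograms of non-time-correlated uniform illumination
#' and computes per-pixel, per-bin weights that equalize the averaged
#' histogram to a flat one while preserving each pixel's total count. Pixels
#' with an all-zero average are flagged and assigned identity weights.
#'
#' @param uniform_runs List of [tcspc_histograms()] (or one), all the same
#'   shape.
#' @return Matrix of weights (pixels x bins) with attribute `flagged_pixels`
#'   (integer indices of dead pixels).
#' @export
build_nonlinearity_correction <- function(uniform_runs) {
  if (inherits(uniform_runs, "lift_tcspc")) uniform_runs <- list(uniform_runs)
  stopifnot(length(uniform_runs) >= 1)
  avg <- Reduce(`+`, lapply(uniform_runs, function(h) h$counts)) /
    length(uniform_runs)
  nb <- ncol(avg)
  tot <- rowSums(avg)
  target <- tot / nb
  w <- matrix(1, nrow(avg), nb)
  live <- tot > 0
  w[live, ] <- target[live] / pmax(avg[live, , drop = FALSE], 1e-12)
  # bins that were exactly zero cannot be equalized; leave them at weight 1
  w[live, ][avg[live, , drop = FALSE] == 0] <- 1
  flagged <- which(!live)
  if (length(flagged)) {
    warning(length(flagged), " pixel(s) with all-zero uniform histogram; ",
            "identity weights assigned", call. = FALSE)
  }
  attr(w, "flagged_pixels") <- flagged
  w
}

# ---- mono-exponential fitting ----------------------------------------------

#' Fit a mono-exponential decay to one TCSPC histogram
#'
#' Fits `A * exp(-t / tau)` on the post-peak tail (from the peak bin to the
#' last bin with at least `min_counts` counts). The default `"mle"` method is
#' the Poisson maximum-likelihood fit — a Poisson GLM with log link, whose
#' linear predictor `log mu = log A - t / tau` is exactly the mono-exponential
#' model; it is essentially unbiased for count data. `"loglinear"` is the
#' classical count-weighted log-linear least squares (faster, slightly biased
#' at low counts) and is also the fallback if the GLM fails to converge.
#'
#' @param decay Numeric vector of counts.
#' @param time_axis_ns Bin-centre times, ns.
#' @param min_counts Tail cutoff (default 5 counts).
#' @param min_bins Minimum number of usable bins (default 5).
#' @param method `"mle"` (Poisson GLM, default) or `"loglinear"`.
#' @return List: `tau_ns`, `amplitude` (at t = 0), `quality` (root mean
#'   deviance per tail bin), `valid` flag, `n_bins` used. Invalid fits
#'   (insufficient signal or non-decaying data) have `valid = FALSE` and
#'   `tau_ns = NA`.
#' @export
fit_monoexponential <- function(decay, time_axis_ns, min_counts = 5,
                                min_bins = 5,
                                method = c("mle", "loglinear")) {
  method <- match.arg(method)
  stopifnot(length(decay) == length(time_axis_ns))
  bad <- list(tau_ns = NA_real_, amplitude = NA_real_, quality = NA_real_,
              valid = FALSE, n_bins = 0L)
  if (all(decay <= 0)) return(bad)
  peak <- which.max(decay)
  tail_ok <- which(decay >= min_counts)
  last <- if (length(tail_ok)) max(tail_ok) else peak
  idx <- seq(peak, last)
  if (length(idx) < min_bins || sum(decay[idx] > 0) < min_bins) return(bad)
  t <- time_axis_ns[idx]
  y <- decay[idx]
  loglin <- function() {
    pos <- y > 0
    fit <- stats::lm.wfit(cbind(1, t[pos]), log(y[pos]), y[pos])
    list(a = fit$coefficients[1], b = fit$coefficients[2],
         q = sqrt(sum(y[pos] * fit$residuals^2) / sum(y[pos])))
  }
  est <- NULL
  if (method == "mle") {
    fit <- try(suppressWarnings(
      stats::glm.fit(cbind(1, t), y, family = stats::poisson())),
      silent = TRUE)
    if (!inherits(fit, "try-error") && fit$converged) {
      est <- list(a = fit$coefficients[1], b = fit$coefficients[2],
                  q = sqrt(max(fit$deviance, 0) / length(y)))
    }
  }
  if (is.null(est)) est <- loglin()
  if (!is.finite(est$b) || est$b >= 0) return(bad)
  list(tau_ns = unname(-1 / est$b), amplitude = unname(exp(est$a)),
       quality = unname(est$q), valid = TRUE, n_bins = length(idx))
}

#' Per-pixel lifetime map from a time-resolved image stack
#'
#' Runs [fit_monoexponential()] at every pixel whose time-integrated
#' intensity passes `intensity_quantile` of the nonzero-pixel distribution.
#'
#' @param cube Array `N x N x T` of counts per time bin.
#' @param time_axis_ns Bin-centre times.
#' @param intensity_quantile Mask threshold on total intensity relative to
#'   the brightest pixel (default 0.1, i.e. keep pixels above 10 percent of
#'   peak).
#' @param ... Passed to [fit_monoexponential()].
#' @return Object of class `lift_lifetime_map`: matrices `tau_ns`,
#'   `amplitude`, `quality` and logical `mask` (valid fits only).
#' @export
fit_lifetime_map <- function(cube, time_axis_ns, intensity_quantile = 0.1,
                             ...) {
  stopifnot(length(dim(cube)) == 3)
  N1 <- dim(cube)[1]; N2 <- dim(cube)[2]
  total <- apply(cube, c(1, 2), sum)
  thr <- intensity_quantile * max(total)
  tau <- matrix(NA_real_, N1, N2)
  amp <- matrix(NA_real_, N1, N2)
  qual <- matrix(NA_real_, N1, N2)
  mask <- matrix(FALSE, N1, N2)
  for (i in seq_len(N1)) for (j in seq_len(N2)) {
    if (total[i, j] < thr) next
    ft <- fit_monoexponential(cube[i, j, ], time_axis_ns, ...)
    if (ft$valid) {
      tau[i, j] <- ft$tau_ns; amp[i, j] <- ft$amplitude
      qual[i, j] <- ft$quality; mask[i, j] <- TRUE
    }
  }
  structure(list(tau_ns = tau, amplitude = amp, quality = qual, mask = mask),
            class = "lift_lifetime_map")
}

#' @export
print.lift_lifetime_map <- function(x, ...) {
  cat("<lift_lifetime_map>", sum(x$mask), "valid pixels; tau range",
      paste(signif(range(x$tau_ns[x$mask]), 3), collapse = " - "), "ns\n")
  invisible(x)
}

#' @export
tidy.lift_lifetime_map <- function(x, ...) {
  idx <- which(x$mask, arr.ind = TRUE)
  tibble::tibble(row = idx[, 1], col = idx[, 2],
                 tau_ns = x$tau_ns[x$mask],
                 amplitude = x$amplitude[x$mask],
                 quality = x$quality[x$mask])
}

#' Histogram of per-pixel lifetimes with peak detection
#'
#' @param map A [fit_lifetime_map()] result (or a numeric vector of
#'   lifetimes).
#' @param breaks Bin boundaries (ns) or a number of bins.
#' @param min_peak_frac Peaks below this fraction of the tallest bin are
#'   ignored (default 0.1).
#' @return Tibble of class `lift_tau_hist` (`tau_ns` bin centres, `count`)
#'   with detected modes in `attr(, "peaks_ns")`.
#' @export
lifetime_histogram <- function(map, breaks = 60, min_peak_frac = 0.1) {
  taus <- if (inherits(map, "lift_lifetime_map")) map$tau_ns[map$mask]
          else as.numeric(map)
  taus <- taus[is.finite(taus)]
  if (length(breaks) > 1) {
    # explicit bin edges: outliers beyond the edges are excluded
    taus <- taus[taus >= min(breaks) & taus <= max(breaks)]
  }
  if (!length(taus)) stop("no valid lifetimes to histogram", call. = FALSE)
  h <- graphics::hist(taus, breaks = breaks, plot = FALSE)
  out <- tibble::tibble(tau_ns = h$mids, count = h$counts)
  pk <- pracma::findpeaks(as.numeric(c(0, h$counts, 0)),
                          minpeakheight = min_peak_frac * max(h$counts),
                          sortstr = FALSE)
  peaks <- numeric(0)
  if (!is.null(pk)) {
    bins <- pk[, 2] - 1L      # undo the zero padding
    # refine each mode by a count-weighted centroid over +/- 1 bin
    peaks <- vapply(bins, function(b) {
      sel <- max(1, b - 1):min(length(h$mids), b + 1)
      sum(h$mids[sel] * h$counts[sel]) / sum(h$counts[sel])
    }, numeric(1))
  }
  attr(out, "peaks_ns") <- sort(peaks)
  class(out) <- c("lift_tau_hist", class(out))
  out
}
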