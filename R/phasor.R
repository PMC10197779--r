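# ---- phasor transforms -----------------------------------------------------

#' First-harmonic phasor transform of a decay or spectrum
#'
#' Temporal domain: `G = sum(I cos(w t)) / sum(I)`,
#' `S = sum(I sin(w t)) / sum(I)` at angular frequency `omega` (rad/ns),
#' defaulting to `2*pi / span` of the time axis (one harmonic of the laser
#' period). Mono-exponential decays then fall on the universal semicircle
#' `(G - 1/2)^2 + S^2 = 1/4`, with `tau -> 0` at (1, 0).
#'
#' Spectral domain: the phase angle spans `2*pi` over the wavelength range,
#' `phi(lambda) = 2*pi (lambda - min) / (max - min)`, and `(G, S)` are the
#' intensity-normalized first Fourier coefficients over that phase.
#'
#' Mixtures map to intensity-weighted convex combinations of their pure
#' components' phasors in both domains.
#'
#' @param signal Nonnegative profile (counts per bin).
#' @param axis Bin positions: time (ns) or wavelength (nm).
#' @param domain `"temporal"` or `"spectral"`.
#' @param omega Angular frequency override for the temporal domain, rad/ns.
#' @return Named numeric `c(G, S)`; attribute `omega` (temporal). All-zero
#'   signals return `c(NA, NA)` flagged with attribute `undefined = TRUE`.
#' @export
phasor_transform <- function(signal, axis, domain = c("temporal", "spectral"),
                             omega = NULL) {
  domain <- match.arg(domain)
  stopifnot(length(signal) == length(axis))
  tot <- sum(signal)
  if (tot <= 0) {
    out <- c(G = NA_real_, S = NA_real_)
    attr(out, "undefined") <- TRUE
    return(out)
  }
  if (domain == "temporal") {
    dt <- axis[2] - axis[1]
    span <- axis[length(axis)] - axis[1] + dt
    w <- omega %||% (2 * pi / span)
    phase <- w * axis
  } else {
    rng <- range(axis)
    phase <- 2 * pi * (axis - rng[1]) / (rng[2] - rng[1])
    w <- NULL
  }
  out <- c(G = sum(signal * cos(phase)) / tot,
           S = sum(signal * sin(phase)) / tot)
  if (!is.null(w)) attr(out, "omega") <- w
  out
}

#' Closed-form temporal phasor of a mono-exponential decay
#'
#' `(G, S) = (1 / (1 + (w tau)^2), w tau / (1 + (w tau)^2))` — the point on
#' the universal semicircle for lifetime `tau` at angular frequency `w`.
#'
#' @param tau_ns Lifetime, ns.
#' @param omega Angular frequency, rad/ns.
#' @return Named numeric `c(G, S)`.
#' @export
phasor_monoexp <- function(tau_ns, omega) {
  wt <- omega * tau_ns
  c(G = 1 / (1 + wt^2), S = wt / (1 + wt^2))
}

#' Per-pixel phasor cloud of a time- or wavelength-resolved cube
#'
#' @param cube Array `N x N x B` (B = time or wavelength bins).
#' @param axis Bin positions.
#' @param domain `"temporal"` or `"spectral"`.
#' @param omega Temporal angular frequency override.
#' @param intensity_quantile Pixels below this fraction of the peak total
#'   intensity are excluded.
#' @return Tibble of class `lift_phasor_cloud`: `row`, `col`, `G`, `S`,
#'   `intensity`; attributes `domain`, `omega`.
#' @export
phasor_cloud <- function(cube, axis, domain = c("temporal", "spectral"),
                         omega = NULL, intensity_quantile = 0.05) {
  domain <- match.arg(domain)
  stopifnot(length(dim(cube)) == 3)
  total <- apply(cube, c(1, 2), sum)
  keep <- which(total >= intensity_quantile * max(total), arr.ind = TRUE)
  res <- purrr::map_dfr(seq_len(nrow(keep)), function(ii) {
    i <- keep[ii, 1]; j <- keep[ii, 2]
    gs <- phasor_transform(cube[i, j, ], axis, domain, omega)
    tibble::tibble(row = i, col = j, G = gs[["G"]], S = gs[["S"]],
                   intensity = total[i, j])
  })
  w <- if (domain == "temporal") {
    dt <- axis[2] - axis[1]
    omega %||% (2 * pi / (axis[length(axis)] - axis[1] + dt))
  } else NULL
  attr(res, "domain") <- domain
  attr(res, "omega") <- w
  class(res) <- c("lift_phasor_cloud", class(res))
  res
}

# ---- clustering ------------------------------------------------------------

#' @importFrom mclust Mclust mclustBIC
NULL

#' Cluster-membership probabilities on the phasor plane
#'
#' Fits a full-covariance Gaussian mixture to the `(G, S)` coordinates (the
#' number of components is assumed known a priori, as when the fluorophore
#' panel is known) and returns the per-pixel posterior responsibilities.
#' Deterministic given the seed.
#'
#' @param cloud A [phasor_cloud()] tibble (or any data frame with `G`, `S`).
#' @param n_clusters Number of components (>= 1).
#' @param seed Integer seed.
#' @return The input tibble with probability columns `p1..pn` (rows sum
#'   to 1) and a `cluster` hard assignment; mixture means in
#'   `attr(, "means")` (a `2 x n` matrix, components ordered by increasing
#'   phase angle `atan2(S, G)` so labels are reproducible).
#' @export
cluster_probabilities <- function(cloud, n_clusters, seed = 1) {
  stopifnot(n_clusters >= 1, all(c("G", "S") %in% names(cloud)))
  X <- cbind(cloud$G, cloud$S)
  if (nrow(unique(X)) < n_clusters) {
    stop("clustering error: fewer distinct phasor points than clusters",
         call. = FALSE)
  }
  if (n_clusters == 1L) {
    out <- tibble::as_tibble(cloud)
    out$p1 <- 1
    out$cluster <- 1L
    attr(out, "means") <- matrix(colMeans(X), 2, 1)
    return(out)
  }
  set.seed(seed)
  fit <- mclust::Mclust(X, G = n_clusters, modelNames = "VVV",
                        verbose = FALSE)
  if (is.null(fit)) stop("clustering error: mixture fit failed", call. = FALSE)
  z <- fit$z
  mu <- fit$parameters$mean
  ord <- order(atan2(mu[2, ], mu[1, ]))
  z <- z[, ord, drop = FALSE]
  mu <- mu[, ord, drop = FALSE]
  out <- tibble::as_tibble(cloud)
  for (k in seq_len(n_clusters)) out[[paste0("p", k)]] <- z[, k]
  out$cluster <- max.col(z)
  attr(out, "means") <- mu
  out
}

# ---- amplitude-fraction unmixing -------------------------------------------

#' Forward map from amplitude fractions to cluster probabilities
#'
#' For the four-component panel in which the lifetime phasor separates
#' component 3 from {1, 2, 4} and the spectral phasor separates component 1,
#' {2, 3} and component 4:
#' `paL = f3`, `pbL = f1 + f2 + f4`, `paT = f1`, `pbT = f2 + f3`,
#' `pcT = f4`.
#'
#' @param f Data frame / tibble with columns `f1..f4` (rows on the simplex).
#' @return Tibble with `paL`, `pbL`, `paT`, `pbT`, `pcT`.
#' @export
fractions_to_probabilities <- function(f) {
  f <- tibble::as_tibble(f)
  stopifnot(all(c("f1", "f2", "f3", "f4") %in% names(f)))
  tibble::tibble(paL = f$f3,
                 pbL = f$f1 + f$f2 + f$f4,
                 paT = f$f1,
                 pbT = f$f2 + f$f3,
                 pcT = f$f4)
}

#' Unmix amplitude fractions from lifetime and spectral cluster probabilities
#'
#' Inverts the linear probability model (see
#' [fractions_to_probabilities()]): `f1 = paT`, `f3 = paL`,
#' `f2 = pbT - paL`, `f4 = pcT`. Out-of-range values are clipped to `[0, 1]`
#' and the quadruple renormalized to sum 1; the pre-clip consistency
#' residual is reported rather than hidden.
#'
#' @param p Data frame with columns `paL`, `pbL`, `paT`, `pbT`, `pcT`; each
#'   probability family (`paL + pbL` and `paT + pbT + pcT`) must sum to 1
#'   within `tol` per row.
#' @param tol Tolerance on the family sums (default 1e-6).
#' @return Tibble with `f1..f4` and `residual` (absolute consistency error
#'   of the overdetermined system before clipping).
#' @export
unmix_fractions <- function(p, tol = 1e-6) {
  p <- tibble::as_tibble(p)
  need <- c("paL", "pbL", "paT", "pbT", "pcT")
  stopifnot(all(need %in% names(p)))
  bad_l <- abs(p$paL + p$pbL - 1) > tol
  bad_t <- abs(p$paT + p$pbT + p$pcT - 1) > tol
  if (any(bad_l) || any(bad_t)) {
    stop("input error: cluster probability families must each sum to 1 ",
         "(worst deviation ",
         signif(max(abs(p$paL + p$pbL - 1), abs(p$paT + p$pbT + p$pcT - 1)), 3),
         ")", call. = FALSE)
  }
  f1 <- p$paT
  f3 <- p$paL
  f2 <- p$pbT - p$paL
  f4 <- p$pcT
  # overdetermined check: pbL should equal f1 + f2 + f4
  residual <- abs(p$pbL - (f1 + f2 + f4))
  raw <- cbind(f1, f2, f3, f4)
  clipped <- pmin(pmax(raw, 0), 1)
  sums <- rowSums(clipped)
  clipped <- clipped / ifelse(sums > 0, sums, 1)
  tibble::tibble(f1 = clipped[, 1], f2 = clipped[, 2],
                 f3 = clipped[, 3], f4 = clipped[, 4],
                 residual = residual)
}
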