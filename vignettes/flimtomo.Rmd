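---
title: "Light-field tomographic FLIM: model, algorithms and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Light-field tomographic FLIM: model, algorithms and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flimtomo)
```

## The acquisition model

A light-field tomographic FLIM system measures a 3-D fluorescent scene
through 1-D projections. The pupil of the objective is divided into `K`
sub-apertures ("views") at normalized coordinates `(u_k, v_k)` in the unit
pupil. For one measurement, a dove prism rotates the selected perspective
image by `theta` and a cylindrical lens collapses it along the y-axis into a
single line of `N` pixels. Because all views look at the same scene, the
perspective image of view `k` is a sheared copy of a common feature kernel:
a plane at defocus `d` appears displaced by `(s*u_k, s*v_k)` pixels, where
the shear parameter `s` depends linearly on depth. The acquired rows —
`n_k` projection angles at view `k`, totalling `Ntheta` angles over all
views — stack into a sinogram `f = F(d) h(d) + noise`, and the whole
operator is linear in the scene. Time-resolved (and spectrally resolved)
scenes factor through the same operator independently per 50 ps TCSPC bin
(per wavelength), which is why every reconstruction here is strictly
per-bin and embarrassingly parallel.

Assumptions inherited from this ray/shear picture: fluorescence adds
incoherently across depth planes; defocus acts as a pure view-dependent
lateral shift (no wave-optical PSF, aberrations or diffraction); detector
noise is Poisson photon counting plus an optional constant background.

### Conventions

Images are `N x N` matrices `[row, col]` with the grid centre at
`((N-1)/2, (N-1)/2)` (0-based). Rotation is counter-clockwise as displayed
with the row index increasing downward; the en-face projection sums over
rows, so a projection row is indexed by image column. `shear_shift()`
returns the 1-D shearing of a sub-aperture projection,
`s*u*sin(theta) - s*v*cos(theta)`. Under the package's axes the
displacement actually seen on the detector for a view sheared by
`(s*u, s*v)` is `s*(u*cos(theta) + v*sin(theta))`, i.e. `shear_shift`
evaluated at `theta + 90` degrees. The two statements are the same physics
with the prism angle measured from the projection axis rather than the
detector axis; the package uses the single internal definition for both
forward projection and refocusing, which is exactly what makes
`refocus_sinogram()` undo the acquisition shear. The test suite pins the
full trajectory: the per-row centroid of a sheared point equals its
rotation sinusoid plus this shift to 1e-10.

### Discretization of the operator

`lift_system_matrix()` assembles `F(d)` as an explicit sparse matrix
(`Matrix::dgCMatrix`, about `2 N^2` nonzeros per angle). Each voxel's
photons are *splatted* onto the detector with a bilinear footprint — the
exact adjoint of inverse-mapping interpolation. Compared with the more
common gather discretization this has two properties worth having in a
photon-counting model: each sinogram row conserves in-field photon mass
exactly, and the transpose of the matrix is the exact adjoint, so filtered
back-projection, CGLS and the FISTA gradient all share one consistent
operator pair. The standalone `rotate_image()` remains a conventional
inverse-mapping bilinear resampler (what one expects of an image-rotation
routine); the tests verify it against a naive per-pixel oracle.

The pixel-driven splat leaves pixel-level ripple in rows at oblique angles
(a known trait of pixel-driven projectors). This is harmless for
reconstruction, but it bounds how exactly a refocus round trip
(`+s` then `-s`, two linear interpolations) can restore a row; the tests
budget 12 % of the row peak for it.

## Reconstruction

**Filtered back-projection.** Rows are ramp-filtered using the band-limited
discrete ramp (built in real space, transformed once per padded length)
with Hann apodization by default — sparse-view data amplify high
frequencies, and the Hann roll-off is the standard remedy; `filter = "ramp"`
gives the unapodized version. Back-projection is the exact adjoint, scaled
by `pi / (2 * Ntheta)`. One test feeds the identical sinogram to this FBP
and to scikit-image's `iradon` (via the command-line `python`) and requires
the two PSNRs against the phantom to agree within 0.5 dB; the angle sign is
opposite between the two conventions and an odd `N` aligns their centre
pixels.

**FISTA.** `fista_reconstruct()` minimizes
`||f - F h||^2 + mu * phi(h)` with proximal-gradient steps, momentum, a
step size `1/L` from 20 power iterations on `F'F` (safety factor 1.05), the
regularizer applied as a denoising step, and a nonnegativity projection
each iterate (photon counts cannot be negative). Two details:

* *Monotone variant.* Plain FISTA is not monotone; the implementation keeps
  the better of the proximal candidate and the previous iterate (the
  standard monotone-FISTA safeguard), so the reported objective trace is
  non-increasing — a property the tests assert.
* *Denoiser.* The default regularizer is isotropic total variation solved
  by 10 Chambolle dual-projection iterations per proximal step
  (`tau = 0.125`). `denoiser` also accepts any function
  `(image, weight) -> image`, which is the plug-in point for heavier
  denoisers such as a BM3D binding; only TV ships with the package.

With `mu = 0` the method reduces to projected-gradient least squares and is
cross-checked against an independent conjugate-gradient solver (1 %
relative image error on an overdetermined, noiseless instance — both run to
tight tolerance, since the comparison is only meaningful once both have
converged).

**Choosing `mu`.** Noiseless or compressive runs default to `mu = 0.05`
with 150 iterations; for the photon-budget protocol the package uses a
noise-matched weight `mu = 4 * peak / sqrt(M)` — four times the Poisson
standard deviation of the brightest projection pixel expressed in
clean-data units — so regularization strength tracks the shot-noise level
across budgets, in the spirit of the discrepancy principle. These defaults
were fixed by the package's own simulation studies (the acceptance script
reruns them); no values from elsewhere are assumed.

**Refocusing, depth sweeps, EDOF.** `refocus_sinogram()` shifts each row by
its view/angle shear displacement with sub-pixel linear interpolation;
`depth_sweep()` reconstructs a list of depths through the geometry's linear
depth-to-shear calibration, `focus_measure()` scores sharpness with the
sum-of-modified-Laplacian in a 5x5 window, and `all_in_focus()` assembles
the per-pixel sharpest values into an extended-depth-of-field image,
breaking exact focus ties toward the smallest depth index (deterministic
and reproducible). `calibrate_depth()` is an ordinary least-squares line
(through `lm()`), with `tidy()`/`glance()` summaries.

## Lifetime and phasor analysis

**SPAD post-processing.** `preprocess_histograms()` applies, in order:
background subtraction clipped at zero (counts cannot be negative);
per-pixel delay correction as a *circular* shift (the TCSPC histogram is
periodic in the laser period, so early counts wrap rather than vanish); and
the nonlinearity correction, a per-bin multiplicative weight table built by
`build_nonlinearity_correction()` from averaged uniform-illumination runs —
the weights flatten the averaged histogram while preserving each pixel's
total count, dead pixels are flagged and given identity weights, and the
correction is idempotent on already-corrected data.

**Mono-exponential fitting.** The decay model `A * exp(-t/tau)` is fit on
the post-peak tail (peak bin to the last bin with at least 5 counts;
at least 5 usable bins). The default fitter is the Poisson maximum
likelihood estimate: a Poisson GLM with log link, whose linear predictor
`log mu = log A - t/tau` *is* the mono-exponential model. The classical
count-weighted log-linear least squares (`method = "loglinear"`, also the
fallback when the GLM fails) is noticeably biased on count data — on
Poisson draws from a 1.5 ns decay with 1e4 photons its mean estimate sits
about 1.6 % high, while the GLM is unbiased to well within sampling error —
which is why the MLE is the default rather than an optional refinement.
Non-decaying or empty pixels return an invalid-fit flag and are masked.

**Phasors.** `phasor_transform()` computes the first-harmonic Fourier
phasor normalized by total intensity. Temporal domain:
`G = sum(I cos(wt))/sum(I)`, `S = sum(I sin(wt))/sum(I)` with
`w = 2*pi / span` of the histogram window (one harmonic of the laser
period) unless overridden — mono-exponential decays then fall on the
universal semicircle `(G - 1/2)^2 + S^2 = 1/4`, mixtures strictly inside,
and mixtures map to intensity-weighted convex combinations. Spectral
domain: the phase spans `2*pi` over the wavelength range. These are the
package's documented conventions; other harmonics are a parameter away.

**Clustering and unmixing.** `cluster_probabilities()` delegates to a
full-covariance Gaussian mixture (`mclust`, `modelNames = "VVV"`) with the
number of clusters assumed known a priori, as it is when the fluorophore
panel is known; components are re-ordered by phasor phase angle so labels
are reproducible, and the identity of each cluster (which fluorophore it
is) remains a user declaration, never an inference. `unmix_fractions()`
inverts the linear probability model `paL = f3`, `pbL = f1+f2+f4`,
`paT = f1`, `pbT = f2+f3`, `pcT = f4` under `sum(f) = 1`: the solution is
`f1 = paT`, `f3 = paL`, `f2 = pbT - paL`, `f4 = pcT`, clipped to `[0, 1]`
and renormalized, with the pre-clip consistency residual of the
overdetermined system reported rather than hidden. The inversion composed
with the forward map is the identity on the simplex, exactly, and the tests
check it on random simplex draws. This particular map assumes the panel's
separability structure (the lifetime phasor isolates component 3, the
spectral phasor isolates components 1 and 4); other panels need their own
assignment.

## The synthetic-data generator

`make_phantom()` provides the three study objects: the standard modified
Shepp-Logan (complex object, peak 1), a programmatic sparse three-bar
resolution target (the operative property is sparsity, not the trademarked
chart artwork), and 3-D bead volumes. Beads come in three diameter classes
(4, 6, 10 µm at 0.9 µm/pixel sampling) carrying mono-exponential lifetimes
1.5, 3.4 and 4.0 ns — the mixed-bead regime with one fast and two close
slow species — placed by rejection sampling with a minimum centre
separation of one diameter; with `time_bins > 0` the scene gains a 50 ps
TCSPC axis, and optional Gaussian emission spectra give the 5-D
`(x, y, z, t, lambda)` variant. Everything is deterministic given the seed.

`apply_shot_noise()` reads "a photon budget of `M`" as Poisson statistics
with expected count `M` at the brightest element (shot noise `sqrt(M)`),
which is the physics of photon counting. The default depth-to-shear slope
is 0.5 pixels/µm, a round value in the range such systems calibrate to; it
is a geometry parameter, not a fitted constant.

What the generator does *not* emulate: optical blur and aberrations,
detector afterpulsing/crosstalk, spatially structured dark counts,
multi-exponential decays, autofluorescence backgrounds, or sample motion.
Passing tests therefore demonstrate correctness of the algorithms under
the stated ray/shear + Poisson model, not instrument-grade performance on
tissue.

## Simulation studies and problem sizes

Two protocols are first-class operations. `run_cr_sweep()` varies the
compression ratio on a noiseless object and records PSNR/SSIM of the
FISTA + TV reconstruction; `run_photon_sweep()` keeps a constant
non-compressive plan, scales the clean sinogram to peak budget `M`, draws
Poisson counts and averages PSNR over seeds. The suite runs these at the
sizes a laptop handles comfortably — the bar target at `N = 180` with 20
angles (CR 9, where sparse objects stay above SSIM 0.9), Shepp-Logan at
`N = 128` with `M in {16, 64, 128, 256, 1024}` over five seeds (PSNR
crosses 20 dB between `M = 16` and `M = 64` and grows monotonically), and
the end-to-end bead pipeline at `N = 64` with 160 bins — and
`scripts/acceptance.R` recomputes the three headline numbers from scratch.

## Numerical details and degenerate inputs

* Power iteration starts from a fixed deterministic vector, so Lipschitz
  estimates (and hence reconstructions) do not consume RNG state.
* `fista_reconstruct()` stops on a 1e-5 relative change of the proximal
  candidate; hitting `max_iters` returns the best iterate with a warning.
* Empty depth lists, single-depth calibrations, all-zero decay pixels,
  all-zero sinogram rows in the centre calibration, probability families
  not summing to 1, degenerate phasor clouds and K > Ntheta plans all raise
  typed errors up front rather than propagating NaNs.
* `lifetime_histogram()` with explicit bin edges excludes out-of-range
  outlier fits (noisy tail pixels can fit to arbitrarily long lifetimes);
  peak locations are refined by a count-weighted centroid over one
  neighbouring bin each side.
* Containers round-trip bit-exactly through single-file RDS; TIFF exports
  are 32-bit float but the writer stores `[0, 1]`, so out-of-range data are
  normalized by their maximum and the scale is returned (and recorded in
  the pipeline manifest). Quantitative tables always also ship as CSV.

## Package shape

Image-valued objects (scenes, sinograms, reconstructions, maps) are plain
matrices/arrays in light S3 containers — the natural currency of image
analysis; everything naturally tabular (angle plans, calibrations, phasor
clouds, sweep reports, lifetime histograms, fraction tables) flows as
tibbles through dplyr verbs, fitted calibrations have broom-style
`tidy()`/`glance()` methods, and each result type has an `autoplot()`
ggplot2 display.

## Known limitations

Reconstruction is plane-by-plane refocusing plus 2-D inversion, not a joint
3-D deconvolution; out-of-plane content appears as structured defocus
background. The forward model's view layout (a ring of radius 0.8 in the
unit pupil by default) is configurable but the instrument's actual lattice
is a calibration input, not something the package can infer. The
compressive recovery guarantees are empirical — sparse targets at CR 9,
complex objects needing lower CR — and no attempt is made at learned
enhancement of the reconstructions.
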