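# flimtomo

Light-field tomographic fluorescence lifetime imaging (FLIM), as a
desk-scale R toolkit: simulation of the acquisition, tomographic and
compressive reconstruction with depth refocusing, and lifetime/phasor
analysis of the recovered time-resolved images.

## The problem and who this is for

Time-domain FLIM with single-photon detectors normally pays for its
picosecond timing with scanning: a point- or line-scanning system needs
`N*N*Nz` or `N*Nz` steps for an `N x N x Nz` volume. A light-field
tomographic microscope sidesteps this by selecting pupil sub-apertures
(views) and optically compressing each rotated perspective image into a
single 1-D *en-face* projection, which a linear SPAD array reads out with a
full TCSPC histogram per pixel. One measurement at prism angle `theta` and
view `k` is

```
f_k(theta) = T R_theta P_k ,        P_k = B_k(d) h(d)
```

where `R_theta` rotates the image (a dove prism at `theta/2`), `T` sums
along the y-axis, and the view images `P_k` are sheared copies
`h(x - s*u_k, y - s*v_k)` of a common feature kernel `h(d)` at depth `d`
with shear parameter `s(d)`. Stacking the acquired rows gives a
view-partitioned sinogram `f = F(d) h(d) + sigma`; with `Ntheta = N` angles
the acquisition is non-compressive, with `Ntheta < N` it is compressive at
compression ratio `CR = N / Ntheta`. Images are recovered by filtered
back-projection or by FISTA on

```
argmin_h || f - F(d) h ||_2^2 + mu * phi(h)
```

with a total-variation denoiser as the regularizer, time bin by time bin for
time-resolved data. Per-pixel decays are then fit with a mono-exponential
(Poisson MLE), and temporal/spectral phasor transforms with Gaussian-mixture
cluster probabilities unmix fluorophore amplitude fractions
(`f1..f4` from the lifetime probabilities `paL, pbL` and spectral
probabilities `paT, pbT, pcT`).

The package is for imaging scientists who want to explore this acquisition
scheme — angle budgets, photon budgets, view layouts, depth calibration —
without the instrument: every input is synthesized by the package itself
(bead volumes with known lifetimes, Shepp-Logan, sparse bar targets,
Poisson shot noise at a stated peak photon budget `M`).

## Worked example

A sparse bar target acquired compressively at CR = 9 (20 of 180 angles,
15 views), reconstructed with FISTA + TV:

```r
library(flimtomo)

geom <- lift_geometry(N = 180, K = 15, Ntheta = 20)
geom
#> <lift_geometry> N = 180  K = 15  Ntheta = 20  CR = 9
#>   rows per view n_k: 2 2 2 2 2 1 1 1 1 1 1 1 1 1 1
#>   depth-to-shear: s(d) = 0.5 * d + 0  (pixels, d in um)

compression_and_reduction(N = 180, Ntheta = 180, K = 15)
#> # A tibble: 1 × 3
#>      cr point_scan_factor line_scan_factor
#>   <dbl>             <dbl>            <dbl>
#> 1     1              2700               15

bars <- make_phantom("usaf_bars", N = 180)
sino <- forward_sinogram(bars, geom)
rec  <- fista_reconstruct(sino, config = recon_config(mu = 0.05,
                                                      max_iters = 150))
image_metrics(rec, bars, data_range = 1)
#> # A tibble: 1 × 2
#>   psnr_db  ssim
#>     <dbl> <dbl>
#> 1    31.1 0.994
```

The scanning-reduction table says a non-compressive `N = 180`, `K = 15`
acquisition replaces 2700 point-scanning steps (or 15 line-scanning steps)
per effective depth stack; the reconstruction metrics say 20 projections
suffice for a sparse object (SSIM 0.994 against the ground truth). The same
calculators cover resolution bookkeeping — deconvolving a 4-pixel bead image
from a measured 4.6 µm FWHM at 0.9 µm/pixel:

```r
deconvolved_width(4.6 / 0.9, known_ws = 4)
#> # A tibble: 1 × 2
#>   width width_px
#>   <dbl>    <dbl>
#> 1  2.11        2      # 2 px * 0.9 um = 1.8 um lateral resolution
```

For the full chain — three bead populations (1.5 / 3.4 / 4.0 ns), forward
projection per 50 ps time bin, Poisson noise, per-bin reconstruction,
per-pixel MLE lifetime fits — see the methods vignette
(`vignettes/flimtomo.Rmd`); the resulting pixel-lifetime histogram shows
three peaks at the bead lifetimes.

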