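# ccrics

Dual-color **c**ross-**c**orrelation **R**aster **I**mage **C**orrelation
**S**pectroscopy for R.

`ccrics` quantifies molecular coincidence — typically the intactness of a
DNA probe carrying a green and a red fluorophore at its two ends — from
two-channel raster-scanned confocal time-lapse images, and maps it in
space and time.  Nuclease cleavage separates the two labels, so the loss
of cross-correlation between the detection channels reads out degradation
directly in living cells, where bulk assays cannot localize it.  The
package is aimed at fluorescence-fluctuation spectroscopists and
quantitative cell biologists with photon-count image stacks (multi-page
TIFF) and a calibrated confocal geometry.

## Method in brief

A raster scan samples pixel `(row, col)` at time
`row·τ_l + col·τ_p`, so diffusing molecules imprint a spatial
correlation over pixel lags `(ξ, ψ)` that is fitted with

    G(ξ, ψ) = S(ξ, ψ) · G_D(ξ, ψ)

    S   = exp(−[(δr·ξ/w0)² + (δr·ψ/w0)²] / [1 + 4D(τ_p ξ + τ_l ψ)/w0²])
    G_D = (γ/N) · (1 + 4D(τ_p ξ + τ_l ψ)/w0²)^−1
                · (1 + 4D(τ_p ξ + τ_l ψ)/w_z²)^−1/2

with `γ = 0.35` for a 3D Gaussian observation volume, fitted along the
fast axis (`ψ = 0`) with `N` and `D` free.  From the green and red
autocorrelation amplitudes (`N_g`, `N_r`) and the apparent
cross-correlation molecule number (`N_c`):

    N_gr = N_g·N_r / N_c        RCA = N_gr / N_g  =  N_r / N_c

RCA — the relative cross-correlation amplitude — is the fraction of
green-labeled molecules that still carry the red label.  The pipeline
(detrend → per-ROI correlation → 10-frame averaging → fit → RCA) is run
either on the whole field or on a half-overlapping 64-px ROI grid
(1024×1024 images tile into the standard 32×32 grid), producing
intensity-modulated RCA maps, ROI time courses, and exponential
decay-rate fits.

A compiled Brownian-dynamics simulator (`simulate_stack()`) scans point
emitters through a 3D Gaussian PSF pixel-by-pixel with Poisson noise and
known ground truth (particle numbers, `D`, double-labeled fraction), so
every stage of the pipeline is testable without microscope data.

## Worked example

Simulate a half-degraded probe population (50% double-labeled, 50%
cleaved into independent single-labeled halves) and analyze it blind:

```r
library(ccrics)

cfg <- solution_protocol(fraction_double = 0.5, n_particles = 100, D = 100,
                         n_frames = 20, n_rows = 128, n_cols = 128,
                         total_time = 20 * 128 * 128 * 12.8e-6, seed = 42)
sim <- simulate_stack(cfg)
res <- ccrics_analysis(sim$green, sim$red, cfg$geometry, detrend_window = 3)
res
#> ccRICS result [ok]: N_g = 0.6661, N_r = 0.613, N_c = 1.25, N_gr = 0.3267
#>   RCA = 0.4905   (D_g = 85.24, D_r = 99.2 um^2/s)
```

The fitted RCA (0.49) recovers the configured intact fraction (0.50):
about half the green-labeled molecules still carry the red label.  `N_g`
and `N_r` are apparent molecule numbers in the observation volume
(inflated by background and detrending by a known, RCA-invariant factor;
see the methods vignette) and `D` is recovered near its true
100 µm²/s.  Degradation kinetics are fitted from an RCA time course:

```r
tmin <- seq(0, 12, by = 0.6)                      # minutes
set.seed(1)
rca_t <- 0.7 * exp(-0.35 * tmin) + 0.02 + rnorm(length(tmin), 0, 0.02)
fit_rca_decay(tmin, rca_t)
#> decay_fit: RCA(t) = 0.6876 * exp(-0.3455 t) + 0.02569  (k_se = 0.0188, SSR = 0.00629)
```

i.e. a degradation rate of 0.35 min⁻¹ recovered with its standard
error.  For spatial mapping use `map_rca()` / `render_map()` /
`roi_timecourse()`, or the CLI
(`inst/cli/ccrics simulate|correlate|fit|map|decay|run`) for on-disk
workflows with TIFF input and CSV/JSON/PNG output.

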