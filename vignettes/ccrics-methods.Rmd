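---
title: "Cross-correlation RICS: model, simulator and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-correlation RICS: model, simulator and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ccrics)
```

## The measurement problem

A raster-scanned confocal image is not an instantaneous snapshot: the beam
visits each pixel at a known time, `t(row, col) = row * tau_l + col *
tau_p`.  Molecules diffusing through the focus therefore imprint a
characteristic *spatial* correlation on the image whose shape along the
fast axis (pixel lag $\xi$, time step $\tau_p$) and slow axis (line lag
$\psi$, time step $\tau_l$) encodes their concentration and mobility.
Raster image correlation spectroscopy (RICS) fits this correlation to
recover the mean molecule number $N$ in the observation volume and the
diffusion coefficient $D$.

The dual-color extension (ccRICS) computes, besides the per-channel
autocorrelations $G_g$ and $G_r$, the cross-correlation $G_c$ between the
green and red detection channels.  Only molecules carrying *both* labels
produce coincident fluctuations, so the cross-amplitude reports the
double-labeled fraction.  The application this package targets is
tracking the degradation of DNA probes labeled with spectrally distinct
fluorophores at their two ends: nuclease cleavage separates the labels
and abolishes the cross-correlation while leaving both autocorrelations
intact.

## Model

The fitted model factorizes into a laser-scanning term and a 3D
free-diffusion term, $G(\xi, \psi) = S(\xi, \psi)\, G_D(\xi, \psi)$:

$$S(\xi,\psi) = \exp\left(-\,\frac{(\delta r\,\xi/w_0)^2 +
(\delta r\,\psi/w_0)^2}{1 + 4D(\tau_p\xi + \tau_l\psi)/w_0^2}\right),
\qquad
G_D(\xi,\psi) = \frac{\gamma}{N}
\left(1 + \frac{4D(\tau_p\xi+\tau_l\psi)}{w_0^2}\right)^{-1}
\left(1 + \frac{4D(\tau_p\xi+\tau_l\psi)}{w_z^2}\right)^{-1/2}.$$

Here $\delta r$ is the pixel size, $w_0$ and $w_z$ the lateral and axial
$1/e^2$ radii of the observation volume, and $\gamma = 0.35$
($\approx 2^{-3/2}$) the correction factor for a 3D Gaussian profile, so
that $G(0,0) = \gamma/N$.  The time combination $\tau_p\xi + \tau_l\psi$
enters through its magnitude: the correlation depends on the time
*difference* between the two pixels of a lag pair, so the model is even
under $(\xi,\psi) \to (-\xi,-\psi)$, matching the exact even symmetry of
the ACF estimator.

From the three fitted amplitudes, with $G_c(0,0) = \gamma/N_c$ defining
the *apparent* cross molecule number and
$G_c(0,0) = \gamma N_{gr}/(N_g N_r)$ its mechanistic meaning,

$$N_{gr} = \frac{N_g N_r}{N_c}, \qquad
\mathrm{RCA} = \frac{N_{gr}}{N_g} = \frac{N_r}{N_c}.$$

The relative cross-correlation amplitude (RCA) is the fraction of
green-labeled molecules that still carry the red label — the intact
fraction.  A non-positive fitted cross amplitude (independent channels)
clamps RCA to 0.  The $N_{gr}$ relation is reconstructed from the two
amplitude identities above; any alternative reading of the apparent-$N_c$
definition changes only a constant mapping of $N_c$, not RCA.

### Which "N" the amplitude recovers

For a 3D Gaussian PSF the background-free amplitude is exactly
$G(0,0) = 1/(c\,\pi^{3/2} w_0^2 w_z)$ with $c$ the number density.  In the
$\gamma/N$ parametrization used here this makes the recoverable quantity
$N = \gamma\, c\, \pi^{3/2} w_0^2 w_z$, i.e. the occupancy of the
$\gamma$-weighted focal volume ($c\,(\pi/2)^{3/2} w_0^2 w_z$ at the ideal
$\gamma = 2^{-3/2}$).  `expected_focal_number()` returns this quantity and
the simulator-recovery tests pin it to within a few percent.

Two systematic amplitude effects are worth knowing:

* **Background dilution.** Uniform (uncorrelated) background of mean $b$
  against signal mean $s$ scales every correlation amplitude by
  $(s/(s+b))^2$, inflating all apparent molecule numbers by the inverse
  factor.  Because the factor is common to $G_g$, $G_r$ and $G_c$ when
  the channels are matched, RCA is invariant.  Amplitude-law tests
  therefore run at zero background; RCA tests run with the default
  background.
* **Detrending attenuation.** Subtracting a $w$-frame moving average
  leaves $\delta I_f - \tfrac1w\sum_{j} \delta I_j$; for
  frame-decorrelated dynamics this scales the fluctuation variance by
  $1 - 1/w$, i.e. $2/3$ for $w = 3$ interior frames.  The
  factor is again channel-common, so RCA is invariant, while absolute
  $N$ from detrended data is inflated by $3/2$.

## Pipeline

`ccrics_analysis()` (whole field) and `map_rca()` (tiled) both run:

1. **Detrend** (`detrend()`, window 3): each frame minus the centered
   3-frame moving average, plus the mean of the trend, so slowly varying
   structure (immobile fraction, cell morphology) is removed and the mean
   intensity is restored exactly.  Boundary frames use shrunken one-sided
   windows.  The phrase "substituted for the raw image" admits a second
   literal reading — replacing frames by their moving average — which is
   available as `mode = "replace"`, but correlation of fast fluctuations
   requires removing the slow component, not smoothing into it, so
   subtraction is the default.
2. **Correlate** (`spatial_correlation()`): per frame, about the
   per-frame ROI mean, via zero-padded (linear, non-circular) FFT with
   per-lag overlap normalization, then division by the product of means.
   Linear correlation matters at ROI scale: a 64-px window wraps badly.
   An exact brute-force double-loop oracle pins the definition in the
   tests.
3. **Average** (`average_surfaces()`): per-frame surfaces averaged over a
   10-frame block (sliding by default; disjoint blocks available).
4. **Fit** (`fit_xi_profile()`): nonlinear least squares of
   $S \cdot G_D$ along $\psi = 0$ only.  ACF fits use
   $\xi \in [1, \mathrm{width}/4]$ — zero lag is excluded because shot
   noise is delta-correlated and inflates only $G(0,0)$; CCF fits include
   zero lag (detector noise is independent across channels) and allow a
   negative amplitude, reported as `amplitude_floor` and mapped to
   RCA = 0.  $w_0$, $w_z$, $\gamma$ stay fixed at their calibration
   values; freeing them would make $N$ and $D$ unidentifiable at ROI
   scale.
5. **Map** (`map_rca()`): 64-px ROIs on a half-overlapping anchor
   lattice.  A 1024-px axis yields exactly 32 anchors at stride 32; edge
   windows truncate to the boundary, which is how the printed
   32 × 32 grid count is honored even though only 31 full 64-px windows
   fit.  Low-intensity ROIs (below 1% of the maximum ROI mean by
   default) and failed fits are marked undefined, never interpolated
   over.
6. **Render** (`render_map()`): RCA on a blue-to-red scale, bilinearly
   interpolated across the half-overlapping grid, brightness modulated by
   normalized local mean fluorescence; undefined regions are dark.
7. **Kinetics** (`fit_rca_decay()`): $A e^{-kt} + c$ on ROI time courses
   (minutes).  The offset $c$ is included by default (a probe population
   may plateau); `offset = FALSE` gives the pure decay-to-zero form.

### Fitting strategy

The model is linear in its amplitude $a = \gamma/N$, so for any fixed $D$
the optimal amplitude has a closed form.  The fit therefore reduces to a
1-D problem in $D$: a log-spaced grid spanning four decades either side
of the lag-range-matched scale $D^\ast = w_0^2/(4\tau_p\,\xi_{max})$ is
scanned with the amplitude profiled out, the best bracket is refined by
bounded 1-D optimization, and the exact $D = 0$ boundary is checked
separately.  This replaces the more conventional multi-start 2-D
optimizer: it is deterministic, cannot be trapped by a bad start, and
recovers noiseless model parameters to optimizer precision (tested at
`1e-6` relative).  Degenerate inputs (all-zero profiles, fewer than 8
usable lags, no positive-amplitude solution for an ACF) return a flagged
`status`, never a silent `NaN`.

## The simulator as stated world

`simulate_stack()` realizes exactly the model's assumptions: point
emitters in 3D free diffusion, a 3D Gaussian PSF
($e^{-2(x^2+y^2)/w_0^2} e^{-2z^2/w_z^2}$), and independent Poisson
counting noise per pixel.  Positions advance on the per-pixel time
lattice — Gaussian increments of variance $2D\,\Delta t$ per axis with
$\Delta t = \tau_p$ between pixels, the flyback remainder at line ends,
and the inter-frame gap between frames — because the $\xi$-decay of the
model requires intra-line motion; per-line updates would bias $D$.
Particles wrap periodically in a box that covers the scanned field plus a
$2w_0$ margin laterally and $4 w_z$ axially, keeping the concentration
around the focus stationary.  Double-labeled particles illuminate both
channels from identical positions; `green_only`/`red_only` species model
the cleaved halves.  A `crosstalk` fraction of green signal can leak into
the red channel (default 0).  The inner loop is compiled (Rcpp) and draws
from R's RNG, so a fixed seed reproduces stacks bit for bit.

Defaults mirror the printed solution measurement: 50 frames of 256 × 256
px over 385 s; pixel size 22 nm; dwell 12.8 µs (within the printed
5–50 µs range and the value quoted for the correlation time resolution);
$w_0 = 0.2$ µm — consistent with a pixel "5–10 times smaller than the
focused spot" — and $w_z = 1.0$ µm (a typical 5:1 axial ratio for a
40×/1.2 NA water objective); $\gamma = 0.35$; 100 particles at
$D = 100$ µm²/s, a sensible value for a 30-bp duplex.  Probe brightness
(5 counts per dwell at focus) and background (0.5 counts per pixel) are
not printed anywhere and were chosen once for testability — high enough
that 50 frames determine the amplitudes well, low enough that counts stay
photon-like.  Within this stated world the full pipeline reproduces the
two printed solution RCA bounds: the 100% double-labeled protocol yields
RCA ≈ 1 ≥ 0.686 (ideal labeling meets or exceeds the experimental
labeling fraction) and the independent-label control yields RCA ≈ 0 ≤
0.024.

What a green test does *not* establish: the simulator has no
photophysics (triplet blinking or bleaching — reported unobservable at
this time resolution), no detector afterpulsing, no optical aberrations,
no cell-like heterogeneous background, and labeling is perfect.  The
printed in-cell numbers (P values, per-cell RCA trajectories) depend on
biological material and are out of reach of a desk reproduction; the
solution bounds and recovery properties are what the synthetic world can
honestly check.

## Numerical choices and edge cases

* Correlation lag range defaults to a quarter of each ROI dimension;
  larger lags are overlap-starved in 64-px windows.
* ACF/CCF profiles are folded ($G(\xi)$ averaged with $G(-\xi)$) before
  fitting; the surfaces are symmetric in expectation and exactly so for
  ACFs.
* Constant (zero-variance) images raise an error by default or return an
  all-zero surface (`on_constant = "zero"`), which downstream fitting
  flags as failed; zero-mean images always error (empty/masked ROI).
* `fit_rca_decay` profiles the linear $(A, c)$ pair over a grid in $k$,
  refines by 1-D optimization and reports an asymptotic `k_se` from the
  Jacobian; at $k = 0$ with an offset the collinear pair is resolved as a
  pure offset.  Fewer than 4 points is an error.
* Block times are the mid-times of their frame windows and are strictly
  increasing; decay fits conventionally take minutes.
* ROI time courses report the *sample* standard deviation over the nine
  selected grid cells.
* TIFF I/O is a minimal baseline implementation (uncompressed grayscale,
  both endiannesses, uint8/16/32 and float32/64, multi-page, optional
  2-sample-per-pixel split) because no TIFF package is available in the
  supported dependency set; it is cross-validated against an independent
  reader in development and by bit-identical round trips in the tests.
  Vendor formats (LSM/CZI) are out of scope — convert to TIFF.

## Known limitations

* Fits use the $\psi = 0$ row only, as in the original analysis; a
  global $(\xi, \psi)$ surface fit and two-component diffusion models are
  deliberately out of scope.
* $D$ from 22-nm-pixel scans is weakly identified at slow diffusion (the
  source analysis reports the same difficulty); per-ROI $D$ values are
  exported but the headline statistic is RCA.
* The grid-count convention (anchors, with truncated edge windows) is one
  of two defensible readings of "32 × 32 ROIs of 64 × 64 pixels,
  half-overlapping"; it is configurable in spirit via `roi_size` and
  documented where it matters.
* Rectangular ROIs only; region selection for time courses is manual
  (3 × 3 grid cells), mirroring the white-square readout.
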