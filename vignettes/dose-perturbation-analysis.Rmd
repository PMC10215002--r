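---
title: "Quantifying dose perturbations around high-Z seed implants"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying dose perturbations around high-Z seed implants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seedperturb)
```

## The problem and the model

When a megavoltage photon beam traverses a small high-Z object — the
silver or gold X-ray marker inside an ^125I brachytherapy seed capsule —
secondary electrons backscatter upstream and are attenuated downstream.
On a plane orthogonal to the beam this produces a localized dose
enhancement just upstream of the seed (*build-up*, BU) and a localized
deficit just downstream (*build-down*, BD), each confined to a few mm.

`seedperturb` quantifies these perturbations from paired 2D dose maps:
a reference acquisition $D^{\mathrm{ref}}$ without seeds and a seeded
acquisition $D^{\mathrm{seed}}$ on the same isocenter-referenced grid.
The perturbation statistic is the pointwise relative dose change

$$\Delta D\,(\%) = \frac{D^{\mathrm{seed}} - D^{\mathrm{ref}}}
  {D^{\mathrm{ref}}} \times 100 ,$$

which is invariant under any common rescaling of the two maps — the
reason raw scanner signal can stand in for calibrated dose as long as
signal is proportional to dose over the analysed range (an assumption the
package documents rather than hides; an optional monotone calibration
table is supported in `read_dose_map()`).

Each BU or BD peak in the $\Delta D$ profile is then summarized by a
sign-constrained composite of a Gaussian and a Lorentzian sharing one
center $\mu$:

$$F(x) = F_0 \pm \Big[(1-M)\,H_G\,
  e^{-\left(\frac{x-\mu}{W_G}\right)^2 4\ln 2}
  + M\,\frac{H_L}{4\left(\frac{x-\mu}{W_L}\right)^2+1}\Big],$$

with $W_G$, $W_L$ the FWHM of the components, fitted by least squares
over a $\pm 2.5$ mm window. The fitted peak amplitude (model extremum
minus offset) is reported as the *dose difference* (%) and the numeric
FWHM of the composite term as the *FWHM* (mm). The $\pm$ sign is fixed by
the caller — positive for BU, negative for BD — since each measurement
plane shows a single-signed peak.

## The processing protocol

`run_analysis()` executes, per seed:

1. **Axis averaging** (`axis_average`): mean over pixel rows in a band
   around the seed row, producing a cross-plane profile at native pitch.
2. **Flat-area normalization** (`normalize_to_flat`): division by the mean
   over the 40–60 mm band on either side of the field center, times 100.
3. **Rebinning** (`rebin`): resampling to a 0.1 mm grid that contains
   $x = 0$ exactly.
4. Optional **symmetrization** (`symmetrize`): mirror-averaging about 0.
5. **Cropping** to the in-field window, then **$\Delta D$**
   (`delta_dose`), which refuses mismatched grids and non-positive
   reference values rather than interpolating silently.
6. **Peak fit** (`fit_peak`) at the known seed position (or at the
   `locate_peak()` maximum when positions are unknown), then cluster
   mean/SD via `summarize_cluster()`.

Whether normalization happens before or after the ratio is immaterial for
proportional signals (the flat-band constant cancels in $\Delta D$); the
pipeline normalizes first and records that choice. The flat band is
interpreted as the union of two 1D intervals $40 \le |x| \le 60$ mm on
the profile axis — the analysis is profile-based, so a 1D band matches
the object being normalized.

## Tunable parameters

| parameter | default | unit | why |
|---|---|---|---|
| `flat_band` | (40, 60) | mm | flat-area normalization band |
| `rebin_mm` | 0.1 | mm | reconstruction bin of the protocol |
| `fit_window_mm` | 2.5 | mm | fit range half-width about the peak |
| `band_half_width_mm` | 2 | mm | averaging band; stays inside the uniform core of a capsule footprint |
| `analysis_half_width_mm` | 35 | mm | in-field crop so the reference is strictly positive |
| `n_starts` | 12 | — | multi-start budget of the fit |
| grid spacing | 25.4/150 ≈ 0.169 | mm/px | 150 dpi film scan; 0.1 mm emulates a Monte Carlo scoring grid |
| `noise_sd` | 2 | % | film-dosimetry uncertainty scale |
| amplitude range | 5–23 | % | measured BU/BD magnitude regime |
| width range | 0.5–2.2 | mm | measured FWHM regime |
| seed pitch | 5 | mm | typical inter-seed spacing in a prostate implant |

## Identifiability and the fit

The printed parameterization $(M, H_G, H_L)$ is degenerate: only the
effective amplitudes $A_G = (1-M)H_G$ and $A_L = M H_L$ enter the curve,
and the two offsets only enter as their sum. The optimizer therefore
works in $(F_0, A_G, A_L, W_G, W_L, \mu)$ and reports back with the
convention $H_G = H_L = A_G + A_L$, $M = A_L/(A_G+A_L)$ — any $(M, H)$
pair reproducing the same curve is equivalent.

Three further constraints were found necessary (all diagnosed on
synthetic data, none tuned to a test threshold):

- **Width upper bound = fit window half-width (2.5 mm).** A component
  whose FWHM exceeds the window is indistinguishable from the offset
  inside it; left unbounded, noise trades a large spurious amplitude
  against a large negative $F_0$ (errors of tens of percent were
  observed). Wider bounds remain available via `bounds`.
- **Width lower bound = 2.5 sample pitches** (and 0.05 mm absolute):
  sub-pixel components only ever fit single noisy samples.
- **Offset band** $F_0 \in \mathrm{median}(\Delta D) \pm
  \max(3\,\mathrm{mad}, 0.5)$: a robust corridor around the local
  baseline.

The minimizer is bounded quasi-Newton (L-BFGS-B with analytic gradients)
from deterministic multi-starts, followed by a PORT (`nlminb`) polish.
Starts include an exact linear least-squares solve of $(F_0, A_G, A_L)$
over a 10 × 10 log-spaced width grid — the model is linear in the
amplitudes for fixed widths, so this locates the global basin cheaply and
resolves the classic pseudo-Voigt trap of a small sharp component riding
on a broad one. The original analysis used a spreadsheet
generalized-reduced-gradient solver; the contract here is the minimizer,
not the algorithm. The fit is deterministic given its `seed`.

`locate_peak()` breaks exact ties toward smaller $|x|$ and then toward
the more negative position. The numeric FWHM is found by bisection
(`uniroot`, tolerance $10^{-8}$ mm) on each side of $\mu$; its exact
limits are $W_G$ at $M=0$ and $W_L$ at $M=1$, and mixtures lie between
the component widths.

## Numerical choices

- **Rebinning uses an FMM cubic spline by default**, not linear
  interpolation. Measured on noiseless scenes at the film pitch, linear
  resampling to 0.1 mm clips the amplitude of a 0.5 mm-FWHM peak by
  ≈ 0.24 % of dose — an order of magnitude above the fit's own recovery
  error — while the spline keeps it below 0.02 %. `method = "linear"`
  remains available. Both preserve coincident nodes exactly and are exact
  on linear data.
- All profile-grid comparisons use a $10^{-9}$ mm tolerance; grids are
  never silently interpolated to match.
- Degenerate inputs fail loudly with located messages: non-finite pixels
  (by index), non-rectangular matrices (by row/column), zero or negative
  reference dose (by position), empty averaging bands, all-zero profiles.
- Bilinear rotation clamps cell indices before taking fractional parts,
  so grid nodes — including ones a rounding error outside the grid —
  resample exactly; 180° rotations of centered grids are bit-accurate.
  The resampling error for smooth fields is $O(h^2)$ (about $2\times
  10^{-2}$ % for a 6 mm-FWHM structure on a 0.25 mm grid), which is the
  tolerance the rotation-invariance tests assert; integrated dose is
  conserved to $10^{-6}$ relative.

## The synthetic generator: what it emulates, and what not

`make_scene()` builds a reference map (flat 10 × 10 cm² field: exact
plateau at 100 %, raised-cosine penumbra, zero outside) and a seeded map
(same field plus per-seed perturbations plus an independent noise draw).
Pixel noise is multiplicative Gaussian at 2 % of local value, the scale
of the overall film-dosimetry uncertainty. Seed centers are snapped to
pixel centers so that the cross-plane section through a seed row equals
the 1D composite term exactly — the convention all ground-truth
comparisons use.

The default footprint is a **capsule**: the cross-plane term extruded
along the in-plane axis over the ≈ 4.5 mm length of the seed capsule,
with cosine end caps. Physically, the X-ray marker is an elongated rod
and measured 2D footprints are elongated, not circular; practically, the
capsule means every row within ±2.25 mm of the seed carries the same
cross-section, so the protocol's own band averaging suppresses pixel
noise without attenuating the truth. A radially symmetric footprint
(`footprint = "radial"`) is also provided; with it, only the single
central row carries the exact section, the effective profile noise is
≈ 2.8 % — and at that noise the free-width composite fit is intrinsically
upward-biased by more than 1 % (the bias scales with noise at
≈ 0.45 σ and stems from the width degrees of freedom, as fixing the
shape removes it). This is a property of the prescribed estimator, not of
the generator.

Footprints taper smoothly to zero 5 mm from the seed (cross-plane) and
1 mm beyond the capsule ends, reflecting the observed spatial confinement
of seed perturbations; at realistic pitches (≥ 5 mm) footprints are
therefore exactly non-interacting and per-seed recovery is well defined.
Without the taper, Lorentzian tails couple neighbouring seeds at the
0.1 % level.

A green recovery test therefore establishes: the pipeline returns the
injected amplitude/width parameters of a compact, additive,
capsule-shaped perturbation on an ideally flat, perfectly registered
field with stationary Gaussian noise. It does **not** establish accuracy
under real-film effects the generator omits: scanner lateral-response
artifacts, film grain and calibration-curve nonlinearity, registration
error between acquisitions, partial-volume blurring of the true physical
footprint, or any radiation-transport physics (the generator is
phenomenological; no Z-dependence or energy dependence is modeled).

## Rotational superposition

`superpose_fields()` models multi-beam-direction delivery as a weighted
sum of the single-field map rotated about the isocenter — a deliberately
phenomenological stand-in for a true rotational measurement, since no
transport is simulated. On the standard dipole fixture
(`make_dipole_scene()`: a wide positive BU footprint displaced upstream,
a narrower, deeper BD footprint downstream) the mean residual
$|\Delta D|$ over a central region decreases monotonically as equally
spaced fields are added and converges to the pattern's rotational
average; this reproduces, structurally, the observation that BU and BD
cancel under rotational irradiation. The measured residuals of the
original rotational experiment depend on its physical data and are out of
scope.

## Uncertainty arithmetic

`combine_quadrature()` implements the k = 1 combination
$\sqrt{\sum u_i^2}$; presentation rounds half-away-from-zero to one
decimal (matching how such budgets are printed), while raw values are
kept. With the standard film chain {1.5, 0.5, 1.5} % the combined value
is 2.2 %; adding the beam-calibration component 1.5 % gives 2.6 %.
`replicate_standard_error()` computes the per-position SE of the mean
across replicate films as a percentage of the local mean, averaged over a
caller-chosen region — the region is exposed as a parameter because the
averaging areas used in practice vary.

## Known limitations

- Film scans are consumed as raw red-channel signal; no optical-density
  conversion or scanner color management (out of scope by design).
- Only cross-plane (X) profiles are analysed; in-plane data contribute
  through averaging only.
- The TIFF reader supports uncompressed baseline grayscale/RGB images
  (8/16-bit), which covers flatbed film scans but not compressed or tiled
  variants.
- The symmetrization step assumes the perturbation sits at the field
  center; it is off by default for synthetic scenes (whose truth need not
  be symmetric) and should be enabled only for the film-protocol
  geometry.
- `dose_difference` extrapolates the fitted model's apex; at profile
  noise ≳ 2 % per 0.1 mm bin the estimator acquires a positive bias of
  order 0.5 % per 10 % amplitude. Reduce noise before the fit (band
  averaging, replicates) rather than trusting single noisy fits.
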