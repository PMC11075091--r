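---
title: "Simulating edge-illumination phase-contrast micro-CT with aperture-driven resolution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating edge-illumination phase-contrast micro-CT with aperture-driven resolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eictsim)
```

## The imaging model

Edge illumination (EI) is an x-ray phase-contrast technique built around two
absorbing masks. A *sample mask* upstream of the specimen slices the beam
into narrow beamlets; a *detector mask* in front of the detector covers the
junctions between pixel columns so that each beamlet illuminates the edge of
an exposed pixel area. Refraction in the sample tilts a beamlet by the
transverse gradient of its accumulated phase, shifting it towards or away
from the exposed area and so converting refraction into an intensity change.
The detected intensity per beamlet is

$$ I = I_0 \, e^{-2k\int\beta\,\mathrm{d}z}\;
   C\!\left(x_m - z_{od}\,\partial_x\!\!\int\delta\,\mathrm{d}z\right), $$

where $n = 1-\delta+i\beta$ is the complex refractive index, $k$ the wave
number, $z_{od}$ the sample-to-detector distance, and $C(\cdot)$ the
*illumination curve*: detected intensity versus lateral sample-mask offset,
measured without a sample. Imaging is done at a working point $x_m$ on a
flank of this curve, conventionally where $C(x_m)/C_{\max}\approx 0.5$.

Because each beamlet only reports on the sample strip it traverses, the
in-slice resolution is set by the aperture width $w$ projected to the sample
plane ($w\,m_s$), not by the source or detector point spread functions. The
package exists to simulate exactly this mechanism: a multi-band sample mask
(20, 10 and 5 µm slits plus 10 µm circles, all at a 79 µm period) lets the
operator trade resolution against flux and scan time *at constant
magnification*.

`eictsim` implements the model with geometric ray optics and an effective
monochromatic energy (18 keV; $\lambda[\mathrm{\AA}] = 12.398/E[\mathrm{keV}]$).
Diffraction fringes, polychromaticity, detector cross-talk and scintillator
blur are deliberately out of scope — the image-formation expression above is
the model, and it is what the retrieval assumes too.

## The optical chain and its defaults

The default configuration (`inst/extdata/default_system.json`, loaded by
`default_system()`) describes the reference instrument:

| parameter | default | unit | note |
|---|---|---|---|
| source → sample mask | 69 | cm | |
| sample mask → sample | 3 | cm | |
| source → detector mask | 84 | cm | |
| source → detector | 86 | cm | magnification $M \approx 1.194 \to 1.2$ |
| effective energy | 18 | keV | mean of the Mo spectrum |
| source horizontal FWHM | 70 | µm | Gaussian, projected geometrically |
| sample-mask period $p$ | 79 | µm | line-skipping |
| aperture widths $w$ | 20 / 10 / 5 (slits), 10 (circles) | µm | the resolution dial |
| detector-mask aperture / period | 17 / 98 | µm | |
| pixel pitch | 50 | µm | |
| working fraction | 0.5 | — | positive-slope flank |

All lengths are stored internally in metres; configuration fields carry
explicit unit suffixes. Two printed instrument values cannot both be derived
from the distances: the sample-mask-to-sample magnification quoted as
$m_s = 1.06$ versus $(69+3)/69 \approx 1.043$ from the distances. The
package derives $m_s$ from the distances by default and exposes a
`sample_magnification` override which is stored and flagged on the geometry
object rather than silently reconciled. Similarly the effective vertical
pixel height used in the flux model is a configuration parameter
(default 40 µm).

## Illumination curve and working point

`simulate_illumination_curve()` computes the overlap integral of the
beamlet profile — the aperture top-hat convolved with the geometrically
projected Gaussian source blur — with the detector-mask aperture window, in
closed form (integrals of the normal CDF), replicated over ±3 mask periods.
A brute-force double quadrature oracle in the test suite confirms the
closed form to better than 0.1%.

`choose_working_point()` locates $x_m$ by root finding on the curve model
(so the achieved fraction is exact to the root tolerance, not to the
sampling step) and estimates the slope $C'(x_m)$ from a Gaussian fit of the
sampled curve — the curve is approximately Gaussian shaped, and a fit is
robust to sampling noise; a finite-difference estimator is available via
`slope_method = "finite_diff"`. The two agree to a few percent on the
default system; the small difference is one reason the retrieval round trip
below is percent-level rather than exact.

Only the horizontal direction is modelled: the slits are vertical and both
beamlet formation and refraction sensitivity are one-dimensional per axial
row. Septa are perfectly absorbing by default (`septa_transmission = 0`).

## Phantoms

Two generators stand in for the physical test objects:

* `bar_pattern_phantom()` — groups of vertical bars (default 5/10/20/30 µm
  line widths, i.e. 100 to 16.7 lp/mm, three bars per group, 50% duty
  cycle) embedded in a substrate disc, emulating a chip-in-cylinder
  resolution insert. Rasterization uses 4× supersampling with box
  down-averaging; group bounding boxes and bar phases are returned as
  metadata so the modulation analysis never has to detect bars blindly.
  Default materials (bar $\delta = 1.2\times10^{-6}$, $\beta = 4\times10^{-9}$;
  substrate $\delta = 4.5\times10^{-7}$, $\beta = 1.5\times10^{-9}$) are
  configuration values, chosen so a projection through the disc keeps the
  transmission comfortably inside (0.1, 0.9) at the desk-scale phantom
  diameter — real β values for mm-sized objects would make a 400 µm phantom
  nearly transparent and every test noise-starved.
* `soft_tissue_phantom()` — seeded smooth Gaussian blobs (default σ between
  50 and 90 µm) on a cosine-tapered cylinder, with
  $\delta = 2k\gamma\,\beta$ *by construction*, so the homogeneous-object
  assumption of the retrieval holds exactly and retrieval accuracy can be
  assessed without model mismatch. The blob scale is chosen to emulate
  organ-scale soft-tissue structure at the simulated field of view.

What these phantoms do *not* emulate: anatomy, sub-resolution texture,
material mixtures (γ heterogeneity), and mask fabrication defects. Passing
the round-trip tests therefore demonstrates correctness of the pipeline
under its own assumptions, not robustness to γ mismatch on real tissue
(the `detect_frame()`/`phase_retrieve()` pair does accept mismatched curves
and γ for such experiments).

## Forward simulation

`detect_frame()` evaluates, on a fine lateral grid (one voxel pitch),
the integrand
$e^{-2k\int\beta}\,C(x_m - z_{od}\,g)$ with $g$ the central-difference
gradient of the projected δ, and then averages it over the beamlet
footprint — a top-hat of width $w\,m_s$ at the sample plane — before
sampling at the beamlet lattice (period $p\,m_s$). The footprint average is
essential, not cosmetic: it is the mechanism of aperture-driven resolution.
Point sampling at beamlet centres (available via
`beamlet_averaging = FALSE`) aliases structure finer than the aperture
instead of blurring it, which visibly corrupts the bar-pattern experiment.
The refraction shift itself is evaluated locally inside the averaged
integrand (a rigid-shift model); projections are parallel-beam within a
frame, with magnification applied as a coordinate scale — at $M = 1.2$ the
cone angle is negligible and the downstream processing treats data as
parallel sinograms anyway.

Poisson noise, when enabled, is seeded per frame by a counter-based hash of
(master seed, angle index, frame index), so reordering a trajectory does
not change any frame's noise stream. Flat fields are interleaved every
`flat_cadence` angles and darks prepended. Flats default to 10× the frame
exposure, emulating the standard practice of averaging a burst of flat
frames: a single-exposure flat would carry percent-level noise *shared
across a hundred angles*, which shows up as low-frequency correlated noise
in the reconstruction and dominates every downstream noise property.

One convention deserves note: the curve argument $x_m - z_{od}g$ mixes a
mask-plane offset with a displacement accrued over $z_{od}$. The package
uses this expression literally, in mask-offset units, for both detection
and retrieval, so the two are self-consistent; reinterpreting the shift at
a different plane would rescale $C'$ and γ jointly without changing the
round trip.

## Acquisition schemes

* **Dithered (step-and-shoot)** — at each of $N$ angles the sample is
  stepped through $N_{dith} = \lceil p/w \rceil$ positions one dither step
  ($w\,m_s$) apart (ceiling because 79 is not a multiple of 20, 10 or 5:
  the steps are 4, 8 and 16). An optional per-angle pseudo-random jitter —
  an integer number of dither steps, drawn over one period from a stored
  seed — decorrelates mask defects into pseudo-noise instead of rings.
  Jitter is quantized to the dither step so that its reversal during
  assembly is exact bookkeeping; sub-step jitter would require regridding
  and is out of scope.
* **Cycloidal type 1 (fly scan)** — $N \times N_{dith}$ angles, one frame
  each, the lateral offset advancing one dither step per angular increment:
  the dithered sampling grid sheared in the angle–offset plane, at
  identical sampling density and total exposure, but without step-and-shoot
  overheads.
* **Cycloidal type 2** — one frame per angle with a larger advance per
  frame (e.g. 28 µm at the 20 µm band): sparser sampling for further time
  savings, with an intrinsic low-pass character discussed below.

Translation follows a back-and-forth triangle wave spanning 10 projected
mask periods (configurable), preserving the field of view. `scan_duration()`
sums exposures for fly scans and adds `overhead_per_step_s` per frame for
step-and-shoot; the overhead is a free configuration parameter because
printed step-and-shoot totals fold in unreported motor/readout costs,
whereas fly-scan totals are pure exposure arithmetic (2400 × 1.2 s = 48 min
for the 20 µm band).

## Sinogram assembly

`flat_dark_correct()` converts frames to `(I - dark)/(flat - dark)` on
count rates, with flats linearly interpolated in time between acquisitions.

`interleave_dithered()` places every frame at the lateral position it
actually probed — beamlet position minus the full applied offset, with the
jitter reversed through the stored integer indices — and then resamples
each angle's row onto an exactly uniform grid of pitch $w\,m_s$ with a
natural cubic spline. The resampling step exists because the true
interleaved positions $(b\,p + j\,w)\,m_s$ are only *nearly* uniform
($N_{dith}\,w = 80$ µm versus $p = 79$ µm): an index-based interleave that
pretends they are uniform accumulates a ~1.3% lateral coordinate stretch
across the field, which would displace 5 µm bars by several micrometres at
the field edge.

`regrid_cycloidal()` exploits the structure of the cycloidal lattice rather
than scattered interpolation: (1) each beamlet's measured values are
splined along the angle axis; (2) for each target lateral column, the
angles at which each beamlet crosses that column follow in closed form from
the triangle-wave translation; the beamlet splines are evaluated at those
crossing angles and a second spline through the crossing samples (periodic
at 360°, implemented by replicating the samples at ±360°) gives the column
at the target angles. For type 1 the crossings per column arrive at exactly
the dithered angular rate, so full resolution is preserved; for type 2 the
larger shift per frame means each beamlet spline interpolates across wider
lateral gaps — the scheme's anti-aliasing low-pass behaviour falls out of
the geometry instead of being imposed. Duplicate crossings at turnarounds
are averaged and counted. The default target grid is the dithered pitch
($w\,m_s$) over the fully swept region; for the under-sampled type 2 this
choice (rather than a coarser grid) is deliberate, documented here, and
matches how the dithered and cycloidal datasets are compared.

Linear fields are reproduced to numerical precision away from the angular
wrap; a function linear in angle is not 360°-periodic, so the wrap padding
perturbs the boundary rows with an exponentially decaying reach — the test
suite pins both facts.

## Retrieval and reconstruction

`phase_retrieve()` implements single-image (Paganin-type) retrieval under
the homogeneity assumption $\gamma = \delta/(2k\beta) = \mathrm{const}$:

$$ \int\beta\,\mathrm{d}z \;=\; -\frac{1}{2k}\,
   \log\!\Big( \mathcal{F}^{-1}\Big[ \frac{\mathcal{F}(I/I_0)}
   {1 + i\,2\pi\nu\, z_{od}\,\tfrac{C'(x_m)}{C(x_m)}\,\gamma} \Big] \Big), $$

applied row-wise along the lateral axis (EI sensitivity is 1D), with the
frequency variable ν (cycles per metre, conjugate to the sample-plane
coordinate) written out explicitly, and mirror padding to twice the row
width before the FFT. The sign of the imaginary term follows R's discrete
transform kernel ($e^{-i2\pi kn/N}$, under which
$\mathcal{F}(\partial_x f) = +i2\pi\nu\mathcal{F}(f)$); the filter
magnitude $1/\sqrt{1 + (2\pi\nu z_{od} (C'/C)\gamma)^2} \le 1$ — a pure
low-pass — is convention-independent, and the linearized round trip in the
test suite pins the sign. With γ = 0 the filter is the identity and the
result is pure attenuation. Normalization by the flat happens during
assembly, before retrieval.

`fbp_reconstruct()` is standard parallel-beam filtered back projection with
a Ram-Lak (|ν|) filter in physical frequency units, zero padding to the
next power of two past four row widths, linear-interpolation back
projection, and the weight π/N that handles both \[0°, 180°) and
\[0°, 360°) angle sets (conjugate views average in the sum). Slices come
out directly in β; `beta_to_mu()` converts to the linear attenuation
coefficient $\mu = 2k\beta$.

`modulation_analysis()` averages the slice along the bar direction inside
each group box and evaluates the profile at the known bar and gap centres;
modulation is (peak − trough)/(peak + trough), clipped at 0. Evaluating at
known phases (instead of hunting extrema) is what makes the measure stable
when a group is near or below the resolution limit.

## Noise2Inverse harness

`split_projections()` sends odd-numbered projections to subset A and
even-numbered to subset B (a strict partition; an odd total leaves the
extra projection in A with a warning), and the halves are reconstructed
with doubled angular spacing. `train_and_apply()` fits a pluggable denoiser
on both cross-directions (A→B, B→A) and applies it to the full
reconstruction, or — `combine = "split_mean"` — to each half with the
outputs averaged, the canonical estimator; the two coincide exactly for
linear denoisers because FBP is linear in the sinogram.

Three denoisers satisfy the `fit`/`apply` contract:

* `conv_denoiser()` (default) — a single learned convolution kernel, fit by
  ridge least squares with the ridge shrinking towards the *identity*
  kernel (so a noise-free fit is a no-op). It is the smallest meaningful
  stand-in for a trained CNN: one layer, closed-form training, fully
  deterministic. A U-Net trained for a fixed number of epochs is treated as
  just another configuration of the contract, not a requirement — trained
  network weights are not bit-reproducible across platforms, so all
  guarantees here are property-based.
* `wiener_denoiser()` — a spatially adaptive Lee/Wiener filter whose noise
  variance is estimated from the half-difference (A−B)/2, which contains
  noise only; this mimics the local adaptivity of a CNN at desk scale.
* `smooth_denoiser()` — a fixed Gaussian baseline for tests.

## Problem sizes and numerical choices

The package's own experiments (test suite and worked examples) run at desk
scale, chosen as the smallest sizes at which each effect is clearly
expressed: retrieval round trip on a 256² phantom at 2 µm voxels with 400
angles; the three-band bar-phantom experiment on a 320² phantom at 1.25 µm
voxels with 160/240/320 angles for the 20/10/5 µm bands (angular sampling
scaled with lateral sampling, as on the instrument); cycloidal comparisons
on a 200² phantom with 120 base angles; the denoising benchmark on a 160²
absorption cylinder with 240 angles. Angular ranges are always \[0°, 360°).

Other numerical choices, in one place: bilinear interpolation for rotated
projections with vacuum outside the support; central differences on the
fine (voxel-pitch) grid for the refraction gradient; refraction shifts
beyond the measured curve support are clamped and counted; negative
normalized intensities are clipped to 0 before the log (counted), and a
non-positive filtered intensity is a hard error naming the pixel; duplicate
samples at cycloidal turnarounds are averaged (counted); ties in
working-point root finding cannot occur because the search is restricted to
one monotone flank.

## Known limitations

* Geometric optics: no fringes, no coherence effects; valid in the regime
  the retrieval itself assumes.
* Single-row physics: vertical source blur and out-of-slice resolution are
  not modelled (out-of-slice resolution on the instrument is set by the
  source/detector PSFs, not the mask).
* The illumination-curve shape for circular apertures reuses the 1D slit
  profile with a flux scale; adequate for working-point and flux
  accounting, not for the exact curve shape.
* γ-mismatch and mask-defect robustness are supported as experiments
  (mismatched curve injection, septa transmission) but carry no
  guarantees.
* The cycloidal regridder assumes the ideal triangle-wave trajectory it
  generated; motor positioning errors and knife-edge tracking are out of
  scope (the simulator knows positions exactly).
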