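# eictsim

Simulation and reconstruction toolkit for **edge-illumination (EI) x-ray
phase-contrast micro-CT** with aperture-driven, adjustable in-slice
resolution.

EI places two absorbing masks in the beam: a sample mask that structures
the beam into narrow beamlets, and a detector mask that covers the
junctions between pixel columns so each beamlet illuminates a pixel edge.
Refraction in the specimen tilts a beamlet by the transverse phase
gradient, shifting it on or off the exposed pixel area; the detected
intensity per beamlet is

```
I = I0 · exp(−2k ∫β dz) · C( x_m − z_od · ∂/∂x ∫δ dz )
```

with `n = 1 − δ + iβ` the complex refractive index, `C(·)` the measured
illumination curve and `x_m` the working point (typically the 50% flank).
Because each beamlet reports only on the sample strip it traverses, the
in-slice resolution is set by the mask aperture width — not by the source
or detector blur — so swapping between the 20/10/5 µm bands of a
multi-band mask tunes resolution at constant magnification and field of
view. The package simulates that instrument end to end and reconstructs
its data:

* **system model** — geometry, multi-band mask, detector mask, closed-form
  illumination curves, working-point selection, flux accounting;
* **phantom factory** — bar-pattern resolution phantoms (5–150 µm line
  widths, i.e. 100–3.33 lp/mm) and seeded single-material soft-tissue
  phantoms with exactly constant γ = δ/(2kβ);
* **forward simulation** — beamlet-sampled attenuation + refraction with
  beamlet-footprint averaging (the resolution mechanism), flats/darks and
  per-frame seeded Poisson noise;
* **acquisition** — dithered step-and-shoot scheduling with exact-reversal
  random jitter, cycloidal fly-scan types 1 and 2 (back-and-forth
  translation), scan-duration accounting;
* **sinogram assembly** — flat/dark correction, dithered interleaving,
  shear-aligned spline regridding of cycloidal data;
* **retrieval + reconstruction** — single-image Paganin-type phase
  retrieval (a Fourier low-pass with |H| ≤ 1), Ram-Lak filtered back
  projection, bar-modulation analysis;
* **denoising harness** — Noise2Inverse odd/even projection splitting with
  pluggable denoisers (learned convolution kernel, adaptive Wiener,
  Gaussian baseline).

Intended users: instrument developers and image-analysis researchers who
want a controlled, fully synthetic testbed for EI acquisition schemes,
retrieval settings and denoising strategies before (or instead of)
beamtime.

## Worked example

Simulate a dithered CT scan of a soft-tissue phantom with the 20 µm
aperture band, assemble, retrieve and reconstruct:

```r
library(eictsim)

sys  <- default_system()          # reference geometry + mask bands
geom <- sys$geometry
geometric_magnification(geom)
#> [1] 1.194444

curve <- simulate_illumination_curve(geom, sys$bands$slit20, sys$detector,
                                     source_fwhm_um = 70, i0_rate = 1e4)
wp <- choose_working_point(curve, 0.5)
wp
#> EI working point: x_m = -11.475 um (positive flank), C/Cmax = 0.500, C' = 362.8 /um

phantom <- soft_tissue_phantom(seed = 7, n = 256, voxel_size_um = 2)
traj <- dithered_trajectory(400, sys$bands$slit20, geom,
                            jitter_seed = 11, exposure_s = 1.2)
nrow(traj$entries); scan_duration(traj) / 60
#> [1] 1600
#> [1] 32

frames <- simulate_scan(geom, sys$bands$slit20, phantom, traj, wp)
sino <- interleave_dithered(flat_dark_correct(frames))
sino
#> EI sinogram (dithered, band 'slit20'): 400 angles x 39 lateral samples, pitch 20.870 um

settings <- retrieval_settings(phantom$meta$gamma_m, geom = geom, wp = wp)
slice <- fbp_reconstruct(phase_retrieve(sino, settings))
slice
#> EI reconstructed slice: 39 x 39 px @ 20.870 um, beta in [-1.33e-10, 5.63e-09]
```

Reading the numbers: the geometry magnifies the sample plane by ≈1.2 onto
the detector; the working point sits 11.5 µm off the aligned position,
where the detected intensity is exactly half the curve maximum and the
slope (363 counts/s per µm here) calibrates the refraction sensitivity.
The 400-angle, 4-step dithered scan yields 1600 frames (32 min of pure
exposure at 1.2 s/frame), which interleave into a 400 × 39 sinogram at the
20.9 µm dither-step pitch; retrieval plus FBP returns the slice directly
in β units — the reconstructed interior recovers the phantom's β
(≈ 3–5 × 10⁻⁹) to within a few percent away from the edges, which the test
suite asserts quantitatively.

The same pipeline with `cycloidal_type1_trajectory()` /
`regrid_cycloidal()` reproduces the dithered sinogram from a fly scan at
identical exposure but without per-step overheads (2400 × 1.2 s = 48 min
for the 20 µm band), and `split_projections()` + `train_and_apply()` run
the Noise2Inverse denoising path on any reconstruction.

## Command line

A thin CLI wraps the exported functions:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "eictsim", package = "eictsim"))')
Rscript $CLI trajectory --scheme cyc1 --angles 600 --band slit20 --exposure 1.2 --out traj.csv
Rscript $CLI assemble   --frames frames.tif --traj traj.csv --out sino.tif
Rscript $CLI retrieve   --sino sino.tif --gamma 9.1e-10 --out ret.tif
Rscript $CLI reconstruct --sino ret.tif --out slice.tif
Rscript $CLI analyze-resolution --slice slice.tif --phantom-meta phantom.json --out modulation.csv
Rscript $CLI denoise    --sino ret.tif --denoiser adaptive_wiener --out slice_dn.tif
```

Rasters travel as float32 TIFF stacks with JSON sidecars (axes, scaling,
per-frame metadata); trajectories as CSV with a JSON header; system
configuration as JSON or YAML validated against the documented schema.
See `vignettes/edge-illumination-simulation.Rmd` for the full model
description, parameter rationale and numerical choices.
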