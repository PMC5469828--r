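---
title: "Quantifying the lacuno-canalicular network from label-free THG stacks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying the lacuno-canalicular network from label-free THG stacks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thglcn)
```

## The problem

Osteocytes live in a connected porosity carved into the bone matrix: µm-scale
ellipsoidal *lacunae* joined by sub-µm *canaliculi* (diameter around
0.5–0.7 µm), the lacuno-canalicular network (LCN). Third-harmonic generation
(THG) microscopy images this network without staining: THG is a coherent
nonlinear scattering process that produces signal only at optical interfaces
and sub-focal-volume heterogeneities, so the walls of the porosity light up
over a weaker matrix background while homogeneous regions stay dark.
Simultaneously recorded second-harmonic generation (SHG) maps the collagen
organization (lamellar modulations of ~4–6 µm period), and a dye-filled
fluorescence channel provides the classic confocal-style reference contrast in
which pore *lumina*, not walls, are bright.

`thglcn` implements the full quantitative chain for such data:

1. **Restoration** — an effective 3D PSF (empirically estimated from
   point-like canalicular cross-sections, or a parametric anisotropic
   Gaussian with lateral/axial FWHM 0.35/1.35 µm) and Richardson–Lucy
   deconvolution.
2. **Canalicular segmentation** — multiscale Hessian (Frangi) vesselness,
   hysteresis thresholding, topology-preserving 3D thinning, centerline
   graph extraction.
3. **Lacuna segmentation** — contrast-aware (interface-shell THG mode vs
   lumen-filled fluorescence mode).
4. **Morphometry** — two-edge canalicular diameters, porosity fractions
   (voxel counting for lacunae, a cylinder model along the skeleton for
   canaliculi), signal-to-background ratios, optical resolution, lamellar
   period, cross-channel correlation.
5. **Bone structural units** — cement lines appear as a dip in the THG
   matrix background; a Hessian sheet filter detects them and the complement
   is labeled into BSUs.

Because real tissue volumes cannot be distributed, the package ships a
synthetic phantom generator with exhaustive ground truth; every stage of the
pipeline is validated as a parameter-recovery experiment on these phantoms.

## Conventions

All arrays are `[z, y, x]` with `z` the optical axis; all physical quantities
are micrometres; the voxel with 1-based index `(i, j, k)` has its centre at
`((i − 0.5)·vz, (j − 0.5)·vy, (k − 0.5)·vx)`. The default grid is the
acquisition grid of the reference imaging conditions, 0.2 µm isotropic.

## The phantom generator

`phantom_spec()` + `build_phantom()` realize a parametric bone volume:
ellipsoidal lacunae (explicit or at a number density), mildly curved
canalicular tubes (explicit polylines or generated to a target centerline
length density), optional vascular channels, a sinusoidal lamellar field, and
cement-line sheets swept along z. Geometry is voxelized through a signed
distance field (clamped at ±0.6 µm), which gives sub-voxel-accurate masks,
analytic surface positions for rendering, and voxel-counted ground-truth
porosity fractions.

Key defaults and where they come from:

* **Canalicular diameter 0.57 µm** and **length density 0.139 µm/µm³**: the
  density reproduces a 3.55 % canalicular volume fraction at that diameter
  (`0.139 × π(0.285)² ≈ 0.0355`), the values measured in the reference
  bovine-femur study conditions the fixtures transcribe.
* **Lacuna semi-axes (5, 2.5, 1.5) µm** (long axis in-plane along the
  lamellae): the source material reports no lacunar dimensions, so these are
  literature-typical and must not be read as measured values. The
  bovine-femur fixture uses a lacuna number density of 1.27 × 10⁻⁵ µm⁻³,
  which reproduces a ~0.1 % lacunar fraction.
* **At most 40 canaliculi rooted per lacuna** (literature-typical
  canaliculi-per-osteocyte counts); the rest of the network runs through the
  matrix, mainly along the lamellar normal in `"lamellar"` mode with a ~15°
  angular jitter, isotropically in `"woven"` mode.
* **Noise**: Poisson sampling with the photon budget anchored so that the
  brightest point of a *reference canaliculus* maps to `noise_peak_photons`
  (default 100). Anchoring to the global maximum instead would let a bright
  lacuna shell dim every canaliculus, coupling the noise level to unrelated
  phantom content.

### The THG render model

THG contrast is interface-localized. The render places an anti-aliased
Gaussian shell (σ = half a voxel) on the *analytic* pore surface — a
morphological one-voxel boundary would sit half a voxel inside the surface
and bias every two-edge diameter low by ~0.1 µm. The shell is weighted by
interface orientation, `0.05 + 0.95·(1 − n_z²)²` with `n` the surface
normal: coherent THG responds most strongly to interfaces parallel to the
optical axis, which is precisely why the two *vertical* edges of a
canaliculus are resolved laterally while the top/bottom of the wall
contributes little. Without this weighting the wide axial PSF (1.35 µm
against a 0.285 µm tube radius) projects the whole shell ring onto the
lateral plane and the double-peak signature never appears; with it, the
two-edge estimator is near-unbiased across true diameters 0.4–1.0 µm. The
exponent and baseline were fixed once, by requiring the documented
phenomenology (two resolved edges, an unbiased manual reading), before any
end-to-end evaluation.

The matrix background is additive (whether the real background is additive
or multiplicative with the interface term is not documented; additive is the
simpler model), modulated in antiphase with the SHG lamellar field at 0.3 ×
the SHG relative amplitude (the THG modulation is described as much smaller,
without a number), and dimmed by the cement factor on cement voxels (> 1
models the positive cement contrast of decalcified samples). When a target
canaliculus-to-background ratio is configured (`thg_sbr_target`, fixture
value 3.4), the interface amplitude is solved *on the phantom itself*: the
blurred image is affine in the amplitude, so the realized centerline/background
ratio can be matched exactly. Calibrating on an isolated reference tube
instead overshoots by tens of percent, because neighbouring canaliculi
scatter intensity onto each centerline.

SHG renders the lamellar sinusoid over `shg_base` with dark pores and dark
(collagen-poor) cement; fluorescence renders bright lumina at a configurable
lumen/matrix ratio (fixture 9.3:1).

What the phantoms do **not** emulate: physical THG phase matching, collagen
fibril texture, depth-dependent aberrations, mosaic stitching, registration
errors between modalities. Passing the recovery experiments therefore shows
the analysis chain is correct and unbiased under the stated contrast model
and photon budget, not that it is robust to every artefact of real
acquisitions.

## Restoration

`estimate_psf_from_canaliculi()` averages background-subtracted,
centroid-aligned (sub-voxel, trilinear) patches around user-supplied
candidate cross-sections, rejecting patches that are off-centre by more than
two voxels or that contain another structure on their border; fewer than
five survivors is an explicit failure pointing to the parametric fallback
`gaussian_psf()`. Treating a canalicular cross-section as a point source
overestimates the FWHM by convolution with the ~0.57 µm lumen; no correction
is applied, matching the reference procedure.

`richardson_lucy()` is the standard multiplicative update from a flat
positive initialization, with reflective boundaries (total intensity
conserved to < 0.1 %). The iteration count is not documented in the source
procedure; the default of 20 is a stable contrast/noise trade-off on
phantoms and is configurable. For separable Gaussian PSFs the full iteration
runs in compiled code.

## Canalicular segmentation

`vesselness()` implements the standard Hessian eigenvalue filter with
physical-unit derivatives (anisotropy-aware), σ²-normalization, and response
`(1 − exp(−R_A²/2α²))·exp(−R_B²/2β²)·(1 − exp(−S²/2c²))` for bright tubes
(zero where λ₂ > 0 or λ₃ > 0), maximized over scales. Two deliberate
numerical choices:

* **auto-c** is half the 99.5th percentile of the Frobenius norm over
  *tube-like* voxels (tube eigenvalue signs, R_A > 0.5), not half the global
  maximum. The maximum is extreme-value unstable — it grows with volume size
  and is dominated by any single bright object such as a lacuna shell, which
  measurably scaled tube responses down ~4× between two phantom sizes. The
  quantile form keeps the response invariant under global intensity scaling.
* The pipeline applies the filter after deconvolution with scales
  {0.3, 0.45, 0.68} µm: RL sharpens the two walls, and a 0.2 µm scale then
  responds to each wall separately, braiding the skeleton (~+9 % false
  length). The undeconvolved fluorescence branch keeps the finer
  {0.2, 0.3, 0.45, 0.68} µm set — its tubes are single dim ridges.
  `vesselness_params()` itself defaults to the four-scale set.

`threshold_mask()` offers Otsu, fixed, quantile and **Otsu-seeded
hysteresis** (default in the pipeline, low cut 0.7 × Otsu): the vesselness
response distribution is ~70 % exact zeros with a long tail, and a single
global Otsu cut truncates dim but connected stretches of the network
(centerline recall ~60 % on fixture phantoms, against ~95 % for hysteresis).

`skeletonize3d()` thins the mask with sequential directional border passes
(candidates collected before removal, ordered by the Euclidean distance
transform; only simple points are removed, endpoints preserved), so
connected components, loops and cavities are preserved exactly — asserted in
the tests via component counts and the Euler characteristic. Anisotropic
masks are resampled to isotropic voxels first (classic thinning assumes
isotropic connectivity); all outputs are physical µm coordinates. Chains are
smoothed with a short moving average before length measurement: raw voxel
chains jitter by about one voxel and overestimate length by 10–20 %.
Terminal spurs shorter than `prune_um` (pipeline default 0.9 µm) and
components shorter than 1 µm are removed.

## Lacuna segmentation

Two contrast regimes (`segment_lacunae()`):

* **Lumen mode** (fluorescence): threshold → fill enclosed cavities →
  opening (removes canaliculi thinner than twice the radius) → closing →
  small-component filter. This is the classic published recipe, applicable
  because lumina are solid bright objects.
* **Interface mode** (THG): the shell is bright but its axial caps are dim
  (orientation dependence), and at a 100-photon budget the canalicular wall
  mesh defeats a bright-threshold/open/close approach (measured precision
  0.07). Instead the lacuna is detected as what it is in THG: a *dark cavity
  enclosed in-plane by a bright shell*. Smoothed Otsu → slice-wise hole fill
  → keep cavities whose interior is darker than 0.9 × the background median
  (matrix pockets enclosed by tube walls are bright inside and are rejected;
  measured separation between the two populations is wide: true cavity
  ≈ 0.7, pockets ≥ 1.0) → opening → re-dilation across the shell band →
  closing. Measured on fixture phantoms: recall ≈ 0.9, precision ≈ 0.84,
  lacunar volume fraction within ~8 % of truth.

## Morphometry

**Diameters.** `measure_diameter()` samples a 3 µm profile perpendicular to
the local tangent, strictly in the lateral plane (tangents within 30° of the
optical axis are rejected: the axial PSF is ~4× wider and the two edges are
only resolved laterally). Nine parallel profiles one voxel apart are
averaged to suppress shot noise; the local background (median of the profile
tails) is subtracted; the profile is re-centred on the lumen minimum; the
wall peaks are the nearest prominent maxima flanking the centre within
±0.8 µm (distant bright neighbours must not capture the pairing), refined by
three-point parabolic interpolation. One peak only → FWHM fallback, tagged.
`diameter_distribution()` samples uniformly by length along the skeleton
(seeded), and summarizes the two-edge measurements with a 2.5-MAD outlier
trim (profiles that lock onto a neighbouring structure produce gross
outliers; all raw measurements are retained in the output). Peak-to-peak
distances are reported without deblurring correction, matching the manual
reference procedure.

**Porosity.** Lacunar porosity is voxel counting; canalicular porosity is
the cylinder model `length × π(D/2)²/V` along the skeleton, with chain
length inside the lacuna mask excluded. The fluorescence branch reuses the
THG-measured mean diameter, as the reference analysis did.

**SBR.** Mean intensity at centerline voxels over the mean intensity at
least 1 µm (Euclidean, anisotropy-aware) from any structure; the reciprocal
for CT-like contrast (dark lumina on bright matrix).

**Resolution.** Gaussian + constant fits (Levenberg–Marquardt) to lateral
and axial profiles through an isolated sub-resolution structure;
FWHM = 2√(2 ln 2)·σ; single-voxel spikes fall back to the interpolated
direct FWHM.

**Lamellar period.** Profile detrended by a moving mean over twice the
largest expected period; the period is the parabolic-refined lag of the
first positive-lag autocorrelation maximum; the quoted ± is the standard
deviation of successive peak-to-peak spacings of the detrended profile (the
convention is recorded because the source's ± is not defined); no
autocorrelation maximum → an explicit aperiodic flag.

**Correlation.** The voxel-wise normalized cross-correlation
`⟨(I₁−⟨I₁⟩)(I₂−⟨I₂⟩)⟩ / √(⟨(I₁−⟨I₁⟩)²⟩⟨(I₂−⟨I₂⟩)²⟩)`; constant input is an
explicit error.

## Bone structural units

`detect_cement_lines()` suppresses the LCN with a 1 µm median filter,
inverts the image in negative mode (cement is a dip in the THG background;
decalcified samples flip to positive contrast), applies a Hessian sheet
filter (response where the single large-magnitude eigenvalue is negative),
thresholds (Otsu) and thins slice-wise to one-voxel lines — curve-thinning a
sheet in full 3D would collapse it to a line. `label_bsus()` bridges gaps by
closing, separates with the *dilated* boundary (detected lines that stop
just short of the border, where the reference procedure applied manual
completion, would otherwise not partition the section), labels the
complement, grows labels back through the dilated band, and merges
components below the minimum size into their largest neighbour. The
partition covers the domain and is idempotent — both asserted in tests.
2D sections are the primary use; 3D stacks work but are treated as
experimental.

## Problem sizes, budgets, degenerate inputs

The recovery experiments run on a 60 × 60 × 50 µm³ phantom for diameters
(the volume of the manual reference measurement; about 22.5 M voxels) and
50 × 50 × 20 µm³ for porosity, both at 0.2 µm voxels with a 100-photon
budget — together a few minutes of CPU. Unit tests use 10–30 µm phantoms.
Degenerate inputs have defined behaviour throughout: empty masks skeletonize
to empty graphs, zero-variance volumes give zero vesselness response and an
error for correlation, zero-length centerlines are rejected at spec
construction, fewer than five PSF candidates is an explicit failure, and an
overly dense cement network aborts with advice to reduce the bridging
radius.

## Known limitations

* The contrast model is phenomenological (interface shell + additive
  modulated background), not a physical THG simulation; absolute intensities
  are meaningful only relative to the configured ratios.
* The two-edge diameter estimator reports peak-to-peak distances uncorrected
  for blur; at D ≈ 0.4 µm the bias approaches the ±0.1 µm band.
* Where canaliculi cross or approach each other closer than the axial PSF
  (1.35 µm against a 2.7 µm mean spacing at the reference density), the
  axially smeared wall stripes of neighbours overlap and the composite
  intensity ridge is displaced a voxel or two from each individual axis.
  Skeletons of isolated/resolvable tubes are voxel-exact, and total length
  and porosity stay within a few percent at full density, but point-wise
  centerline accuracy near crossings is limited by the image itself, not by
  the thinning.
* The THG lacuna detector keys on enclosed dark cavities; lacunae truncated
  by the volume border, or overlapping a vascular channel, can be missed or
  merged.
* The fluorescence-branch skeleton under dim, noisy conditions depends on
  the hysteresis seed threshold; gross photon starvation (≪ 50 photons at
  the canalicular peak) degrades recall before it degrades the THG branch.
* 3D BSU segmentation assumes cement sheets roughly parallel to the
  sectioning axis.
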