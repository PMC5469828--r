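# thglcn

Quantitative analysis of the bone **lacuno-canalicular network (LCN)** from
label-free third-harmonic generation (THG) microscopy stacks, with companion
second-harmonic generation (SHG) and dye-filled fluorescence channels.

Osteocytes inhabit a connected porosity in the bone matrix: µm-scale
ellipsoidal *lacunae* linked by sub-µm *canaliculi* (~0.5–0.7 µm diameter).
THG produces signal only at optical interfaces, so the *walls* of this
porosity light up over a weaker matrix background without any staining —
sufficient, at a lateral resolution of ~0.35 µm, to resolve the two vertical
edges of individual canaliculi and to measure their diameter as the two-edge
peak distance. The package implements the full analysis chain for such data
and validates every stage on synthetic phantoms with known ground truth:

* **Phantoms** — `phantom_spec()`, `build_phantom()`, `render_thg()` /
  `render_shg()` / `render_fluorescence()`: parametric bone volumes
  (lacunae, canaliculi, lamellae, cement lines, vascular channels) voxelized
  through a signed-distance field, rendered per modality with PSF blur and
  Poisson noise, with exact masks, centerlines and porosity fractions.
* **Restoration** — `estimate_psf_from_canaliculi()` (empirical effective
  PSF from point-like canalicular cross-sections), `gaussian_psf()`,
  `richardson_lucy()`.
* **Segmentation** — `vesselness()` (multiscale Hessian/Frangi filter, with
  anisotropy-aware physical derivatives), `threshold_mask()` (Otsu, fixed,
  quantile, Otsu-seeded hysteresis), `skeletonize3d()`
  (topology-preserving 3D thinning to a centerline graph),
  `segment_lacunae()` (interface-shell THG mode and lumen-filled
  fluorescence mode).
* **Morphometry** — `measure_diameter()` / `diameter_distribution()`
  (two-edge estimator with FWHM fallback), `porosity_fractions()`
  (voxel-counted lacunar + cylinder-model canalicular porosity),
  `signal_to_background()`, `estimate_resolution()`, `lamellar_period()`,
  `image_correlation()`.
* **Bone structural units** — `detect_cement_lines()` (Hessian sheet filter
  on the THG cement-line dip; positive mode for decalcified samples),
  `label_bsus()`.
* **Pipeline** — `run_pipeline()` chains everything (simulation or TIFF
  input → PSF → deconvolution → vesselness → threshold → skeleton → lacunae
  → metrics, plus optional SHG, BSU and fluorescence branches) and returns a
  classed report; `write_outputs()` writes masks, skeleton tables,
  diameter CSVs and a JSON report. A thin command-line driver lives in
  `inst/cli/lcn.R`.

The core statistic set mirrors standard bone histomorphometry: mean ± sd
canalicular diameter D (two-edge distance), lacunar/canalicular/total
porosity as volume fractions (canalicular = L·π(D/2)²/V along the skeleton
of total length L), signal-to-background ratios per modality, lamellar
period, and the normalized cross-correlation
c(I₁,I₂) = ⟨ΔI₁ΔI₂⟩/√(⟨ΔI₁²⟩⟨ΔI₂²⟩) between channels.

## Worked example

Simulate the bundled bovine-femur fixture (0.2 µm voxels, PSF 0.35/1.35 µm,
canaliculi of 0.57 µm at a 3.55 % volume-fraction density, THG contrast
3.4:1, 100-photon noise peak) at a small demo volume and run the full
pipeline:

```r
library(thglcn)
cfg <- yaml::read_yaml(system.file("extdata", "bovine_femur.yaml", package = "thglcn"))
cfg$phantom$volume_size_um <- c(12, 30, 30)  # (z, y, x) in um
report <- run_pipeline(cfg)
print(report)
```

```
<lcn_report>
  volume: 60 x 150 x 150 voxels at 0.2 x 0.2 x 0.2 um, seed 1
  canalicular diameter: 0.561 +/- 0.037 um (n = 40 two-edge)
  porosity: lacunar 0.000%, canalicular 3.226%, total 3.226%
  canalicular length: 1410.1 um
  THG SBR: 3.86:1
  lamellar period: 5.55 +/- 2.10 um
  correlation THG_FLUO: 0.511
  correlation THG_SHG: -0.408
  correlation FLUO_SHG: -0.322
  fluorescence branch: total porosity 3.068%, length 1340.8 um
```

Reading the output: the two-edge estimator recovers the configured 0.57 µm
diameter to within 0.01 µm; the cylinder-model canalicular porosity (3.23 %)
sits within 10 % of this phantom's voxel-counted ground truth (3.58 %, in
`report$ground_truth`); the SHG lamellar period comes back at the configured
5.6 µm; and the THG/SHG correlation is negative, reflecting the antiphase
matrix modulation of the two contrasts. The fluorescence branch — the
confocal-style recipe without deconvolution — lands within a few percent of
the THG branch, mirroring the cross-modality agreement expected for this
kind of data. (This demo volume draws no lacuna; the fixture's analysis
volume of 50 × 50 × 20 µm³ does.) `summary(report)` prints the stage log
with every realized threshold and auto-selected constant.

## Documentation

The methods vignette (`vignettes/lcn-methods.Rmd`) describes the phantom
contrast model and its deliberate simplifications, the estimator designs,
every numerically consequential default (hysteresis thresholds, vesselness
scales and auto-c, pruning lengths, the lacuna dark-cavity criterion), and
the known limitations.
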