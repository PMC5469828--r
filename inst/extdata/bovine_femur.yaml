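# Bovine femur THG/fluorescence fixture.
# Imaging values (voxel size, PSF FWHM, canalicular diameter, canalicular
# length density reproducing a 3.55 % canalicular fraction, THG
# canaliculus-to-background ratio 3.4:1, fluorescence contrast 9.3:1,
# osteonal lamellar period) follow the reference bovine femur acquisition;
# lacuna dimensions are literature-typical (not reported for this sample)
# with a number density reproducing a 0.10 % lacunar fraction.
# Axis convention: all triples are (z, y, x), z = optical axis, units µm.
seed: 1
phantom:
  volume_size_um: [20.0, 50.0, 50.0]
  voxel_size_um: 0.2
  lacuna_density_per_um3: 1.27e-5
  lacuna_semi_axes_um: [2.5, 1.5, 5.0]
  canalicular_density_um_per_um3: 0.139
  canalicular_diameter_um: 0.57
  canalicular_diameter_sd_um: 0.0
  canalicular_segment_um: 12.0
  orientation_mode: lamellar
  lamellar:
    period_um: 5.6
    direction: [0.0, 1.0, 0.0]
    amplitude: 0.4
  thg_sbr_target: 3.4
  amplitudes:
    matrix_background: 1.0
    lumen_fluorescence_amp: 9.3
    fluo_matrix_amp: 1.0
    shg_base: 1.0
  noise_peak_photons: 100
psf:
  mode: gaussian
  fwhm_lateral_um: 0.35
  fwhm_axial_um: 1.35
deconvolution:
  iterations: 20
diameters:
  n_samples: 100
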