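# Bovine osteon SHG fixture: concentric lamellar modulation of the
# collagen signal, period 5.6 um on average in the reference osteon.
# Axis convention: all triples are (z, y, x), z = optical axis, units µm.
seed: 1
channels: [SHG]
phantom:
  volume_size_um: [5.0, 45.0, 10.0]
  voxel_size_um: 0.2
  lamellar:
    period_um: 5.6
    direction: [0.0, 1.0, 0.0]
    amplitude: 0.5
  amplitudes:
    shg_base: 50.0
  noise_peak_photons: 100
psf:
  mode: gaussian
  fwhm_lateral_um: 0.35
  fwhm_axial_um: 1.35
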