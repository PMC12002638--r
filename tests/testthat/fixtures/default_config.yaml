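grids:
  sted_spacing_nm_zyx:
  - 150.0
  - 20.0
  - 20.0
  confocal_spacing_nm_zyx:
  - 300.0
  - 100.0
  - 100.0
optics:
  sted:
    lateral_fwhm: 50.0
    axial_fwhm: 90.0
    peak_photons: 8.0
    background_photons: 0.02
  confocal:
    lateral_fwhm: 250.0
    axial_fwhm: 600.0
    peak_photons: 30.0
    background_photons: 1.0
segmentation:
  maxima_radius_xy: 5.0
  maxima_radius_z: 2.0
  global_k: 2.0
  gaussfit_sd: 1.5
  max_radius: 20.0
  min_voxels: 3.0
  max_voxels: 20000.0
  smooth_sigma_px: 0.8
  min_threshold_photons: 1.0
thresholds:
  global_k: 2.0
  roi_k: 1.5
overlap:
  confocal_min_px: 2.0
  sted_min_vox: 1.0
bassoon_proximity_nm: 200.0
puncta:
  min_px: 3.0
  max_px: 100.0
  min_dendrite_um: 50.0
density_per_um: 10.0
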