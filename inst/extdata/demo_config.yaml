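# Demo run: synthetic micro-respirator scene with two tumour and two stromal
# patches, oxygen measurement at 20-s intervals for 10 min.
seed: 42
analyte: O2
scene:
  grid_shape: [40, 60]
  pixel_size_mm: 0.1
  initial_o2_pct: 100
  chamber:
    height_mm: 0.1
    reference_height_mm: 0.1
    D_eff_mm2_per_s: 0.0002
  cell_types:
    tumour:
      density: 20000
      k_o2: 2.5e-6
      nucleus_radius_px: 1.5
    stroma:
      density: 6000
      k_o2: 1.25e-6
      nucleus_radius_px: 1.5
  patches:
    - {rows: [6, 15], cols: [6, 15], cell_type: tumour}
    - {rows: [26, 35], cols: [6, 15], cell_type: tumour}
    - {rows: [6, 15], cols: [36, 45], cell_type: stroma}
    - {rows: [26, 35], cols: [36, 45], cell_type: stroma}
acquisition:
  interval_s: 20
  duration_s: 600
  exposure_scale: 1
  read_noise_sd: 5
  shot_noise: true
calibration:
  batch_id: demo-batch
  o2:
    r0: 1.6
    ksv: 0.03
smoothing_factor: 2
rois:
  - {label: tumour_a, patch: 1, group: tumour}
  - {label: tumour_b, patch: 2, group: tumour}
  - {label: stroma_a, patch: 3, group: stroma}
  - {label: stroma_b, patch: 4, group: stroma}
kinetics:
  r2_threshold: 0.99
  min_fraction: 0.3
  min_points: 10
nuclei:
  enabled: true
  pixel_size_mm: 0.005
  params:
    threshold: otsu
    min_area_px: 3
    max_area_px: 200
    declump: intensity
    exclude_border: false
spatial:
  k: 5
  min_area_mm2: 0.1
stats:
  enabled: true
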