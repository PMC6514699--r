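# Example scene list for `leafrect simulate --scenes ...`
scenes:
  - shape: square
    side_mm: 50
  - shape: circle
    diameter_mm: 60
    tilt_deg: 30
    blur_sigma_px: 1
  - shape: leaf
    leaf_template: serrated
    leaf_area_cm2: 35
    plate_width_mm: 160
    plate_height_mm: 120
    tilt_deg: 15
    noise_sd: 3
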