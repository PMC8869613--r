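# Versioned pipeline defaults. Rig geometry follows the published system
# (35 mm lens, 20 um pitch on a 640 x 512 InGaAs sensor, 40 mm baseline,
# 450 mm object distance); matching and enhancement defaults are the
# package's declared choices, calibrated medium coefficients live in the
# package code (see scripts/calibrate_medium.R).
focal_length_mm: 35
pixel_pitch_um: 20
baseline_mm: 40
object_distance_mm: 450
reference_plane_offset_mm: 0
sensor_width_px: 640
sensor_height_px: 512

# vessel enhancement (inputs are quantile-normalized and gamma-compressed
# first so deep, attenuated vessels survive the structureness cut-off)
normalize: true
normalize_quantile: 0.999
normalize_gamma: 0.5
scales: [1, 2, 4, 6, 8]
beta: 0.5
c: .na
threshold: otsu
min_component_size: 50

# semi-global matching
cost: census
census_window: 7
p1: 10
p2: 120
n_paths: 8
lr_tolerance: 1.0
subpixel: true
subpixel_method: equiangular
z_span_mm: 15

# medium / display
band: LP1300
display_range_mm: [-6, -10]
seed: 1
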