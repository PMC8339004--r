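# Benchmark reader-study geometry: 201 posteroanterior radiographs from 21
# nodule-free volumes; 20/53/67/61 radiographs with 0/1/2/3 nodules and
# 370 lesions sized 8/10/15/20 mm in counts 32/111/120/107. Matching radius
# for evaluation is 30 output pixels on the 512 x 512 image.
study:
  n_per_count: {"0": 20, "1": 53, "2": 67, "3": 61}
  size_counts: {"8": 32, "10": 111, "15": 120, "20": 107}
  out_size: 512
  unique_healthy_volume: true
phantom:
  n_volumes: 21
  shape: [128, 128, 128]
  spacing_mm: 2.5
  noise_sd_hu: 20
pool:
  n_shapes: 19
  base_diameter_mm: 10
  irregularity: 0.3
  grid_spacing: 0.5
evaluate:
  radius_px: 30
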