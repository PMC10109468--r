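# Example pipeline configuration: the full seven-montage survey layout with
# the calibrated default volunteer model. Any omitted entry falls back to the
# package defaults (see ?pipeline_config).
montage:
  n_cols: 60
  n_rows: 60
  tile_px_x: 6144
  tile_px_y: 4090
  fov_width_um: 120
  overlap_frac: 0.125
  dwell_s: 8
n_montages: 7
consensus:
  quorum: 3
  max_views: 4
  order_aware: true
review:
  seconds_per_image: 5
  miss_rate: 0
  escalation_rate: 0
census:
  epsilon_um: 10
simulation:
  density_per_cm2: 207
  n_volunteers: 271
master_seed: 1
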