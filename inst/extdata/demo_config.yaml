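# Bundled demonstration configuration: a small 8-day simulated
# experiment (3 pre-lesion days, lesion after day 3, 5 post-lesion
# days) on the full 96-channel array, short sessions for speed.
seed: 424242
out_dir: perilesion_demo
simulate:
  enabled: true
  n_days: 8
  lesion_day: 3
  duration_s: 3.0
  noise_sd_uv: 10.0
  neurons_per_electrode: 12
  lesion:
    enabled: true
    anode: 45
    cathode: 46
    current_ua: 150.0
    duration_s: 45.0
    volume_mm3: 9.2
turnover:
  min_events: 60
grouping:
  max_separation: 4
  acute_limit: 3
  late_window: [4, 7]
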