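{
  "n_subjects": 6,
  "sessions": [1, 2, 3],
  "s3_duration_s": 120,
  "gain_mean": 1.5,
  "gain_sd": 0.5,
  "noise_scale": 0.8,
  "master_seed": 7,
  "windows_per_event": 3,
  "w": 0.8,
  "policy": {"physical_threshold": 45, "mental_threshold": 36}
}
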