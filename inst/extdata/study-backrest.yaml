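# Synthetic backrest flip study: four backrest angles.
kind: backrest_flip
synth:
  angles: [0, 10, 20, 30]
  seed: 20260102
  internal_noise_sd: 0.02
  noise_sd: 0.3
threshold: 0
cushion_split_row: 24
l1_row: 24
trend_method: spearman
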