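# Synthetic whole-chair flip study: five adjustment angles, cushion +
# backrest maps and internal-response values generated per condition.
kind: whole_chair_flip
synth:
  angles: [0, 10, 20, 30, 40]
  seed: 20260101
  internal_noise_sd: 0.02
  noise_sd: 0.3
threshold: 0
cushion_split_row: 24
l1_row: 24
trend_method: spearman
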