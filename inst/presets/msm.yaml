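# Two-state Markov switching (slow <-> fast), ~50-frame dwell times.
EXP_1:
  model: msm
  K_mean: [0.05, 1]
  K_sd: [0.01, 0.1]
  alpha_mean: [0.8, 1.2]
  alpha_sd: [0.05, 0.05]
  M:
    - [0.98, 0.02]
    - [0.02, 0.98]
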