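# Transient dimerization: subdiffusive dimeric state.
EXP_1:
  model: dim
  K_mean: [1, 0.3]
  K_sd: [0.1, 0.02]
  alpha_mean: [1, 0.5]
  alpha_sd: [0.05, 0.02]
  r: 1
  P_b: 1
  P_u: 0.02
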