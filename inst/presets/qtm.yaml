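# Quenched traps: transient immobilization (K = 0, alpha = 0).
EXP_1:
  model: qtm
  K_mean: 1
  K_sd: 0.1
  alpha_mean: 1
  alpha_sd: 0.05
  N_t: 100
  r_t: 1
  P_b: 1
  P_u: 0.05
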