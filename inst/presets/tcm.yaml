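# Transient confinement in osmotic compartments.
EXP_1:
  model: tcm
  K_mean: [1, 0.5]
  K_sd: [0.1, 0.05]
  alpha_mean: [1, 0.8]
  alpha_sd: [0.05, 0.05]
  N_c: 15
  r_c: 6
  transmittance: 0.1
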