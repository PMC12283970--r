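# Single-state negative control: broad (K, alpha) distributions, no switching.
EXP_1:
  model: ssm
  K_mean: 1
  K_sd: 0.2
  alpha_mean: 1
  alpha_sd: 0.1
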