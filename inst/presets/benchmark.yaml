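# A small multi-model benchmark: one experiment per interaction model.
EXP_1:
  model: msm
EXP_2:
  model: dim
EXP_3:
  model: tcm
EXP_4:
  model: qtm
EXP_5:
  model: ssm
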