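time: 2026-09-11 08:02:30
config: /tmp/RtmpzPAVTG/file10f61fab772f/config.yml
config_hash: 8166
seed: 5
  R_turn: 12
  D_react: 70
  D_attack: 400
  D_initial: 130
  beta_step: 30
  n_per_beta: 10
  seed: 5
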