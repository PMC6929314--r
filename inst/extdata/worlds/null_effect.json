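{
  "n_waves": 2,
  "p_baseline": 0.5,
  "name": "null_effect",
  "conf_init": [-0.3, 0.6],
  "conf_trans": [-0.6, 1.0, 0.0],
  "exposure": [-0.8, 0.4, 1.0, 0.8],
  "outcome": [-1.2, 0.0, 0.9, 0.4]
}
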