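{
  "n_waves": 3,
  "p_baseline": 0.3,
  "name": "protective_3wave",
  "conf_init": [-0.2, 0.5],
  "conf_trans": [-0.7, 1.1, 0.7],
  "exposure": [-0.9, 0.3, 0.8, 1.0],
  "outcome": [-1.8, -0.6, 0.7, 0.4]
}
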