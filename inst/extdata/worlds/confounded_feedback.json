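{
  "n_waves": 2,
  "p_baseline": 0.4,
  "name": "confounded_feedback",
  "conf_init": [-0.5, 0.8],
  "conf_trans": [-0.8, 1.2, 0.8],
  "exposure": [-1.0, 0.5, 0.9, 1.2],
  "outcome": [-1.5, 0.5, 0.8, 0.3]
}
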