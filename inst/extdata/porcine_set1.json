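{
  "kBC0": 0.0, "kBC_Ca2": 208.4857, "kCB0": 5907.6526, "kCB_Ca2": 246.3005,
  "fCM1_0": 103.8109, "fM1C_0": 157.6488,
  "kM1M2": 14.6009, "kM2M1": 1.6748, "kM2C": 0.0367,
  "pCa50": 5.65,
  "u1": 1.0, "u2": 1.0, "z1": 1.0, "z2": 1.0, "v": 1.0, "w": 1.0,
  "alpha": 1.0, "alpha_bar": 1.0, "beta": 1.0, "beta_bar": 1.0
}
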