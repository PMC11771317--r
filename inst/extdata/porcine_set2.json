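{
  "kBC0": 0.0, "kBC_Ca2": 243.0357, "kCB0": 1694.7526, "kCB_Ca2": 0.0,
  "fCM1_0": 91.0080, "fM1C_0": 691.6738,
  "kM1M2": 3.2005, "kM2M1": 2.5001, "kM2C": 0.7366,
  "pCa50": 5.65,
  "u1": 1.0, "u2": 15.098, "z1": 1.0, "z2": 1.1346, "v": 1.0, "w": 1.0,
  "alpha": 1.0, "alpha_bar": 1.0, "beta": 1.0, "beta_bar": 1.0
}
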