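{
  "kBC0": 24.3511, "kBC_Ca2": 243.5360, "kCB0": 1592.7530, "kCB_Ca2": 117.5183,
  "fCM1_0": 90.9918, "fM1C_0": 691.7920,
  "kM1M2": 2.6762, "kM2M1": 2.5561, "kM2C": 0.6945,
  "pCa50": 5.65,
  "u1": 1.1055, "u2": 17.0820, "z1": 1.0001, "z2": 1.0, "v": 1.0374, "w": 1.0,
  "alpha": 1.0, "alpha_bar": 0.8296, "beta": 1.0, "beta_bar": 1.0
}
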