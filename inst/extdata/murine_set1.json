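{
  "kBC0": 0.0166, "kBC_Ca2": 0.4370, "kCB0": 2.3633, "kCB_Ca2": 0.3979,
  "fCM1_0": 72.6072, "fM1C_0": 44.2949,
  "kM1M2": 50.6703, "kM2M1": 53.5794, "kM2C": 55.7214,
  "pCa50": 5.63,
  "u1": 1.0, "u2": 1.0, "z1": 1.0, "z2": 1.0, "v": 1.0, "w": 1.0,
  "alpha": 1.0, "alpha_bar": 1.0, "beta": 1.0, "beta_bar": 1.0
}
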