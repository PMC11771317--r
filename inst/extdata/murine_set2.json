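{
  "kBC0": 0.0167, "kBC_Ca2": 1.9370, "kCB0": 2.3633, "kCB_Ca2": 0.3979,
  "fCM1_0": 43.0072, "fM1C_0": 50.2949,
  "kM1M2": 39.5703, "kM2M1": 47.3794, "kM2C": 47.2714,
  "pCa50": 5.63,
  "u1": 1.0, "u2": 2.2208, "z1": 1.0, "z2": 1.0, "v": 1.0, "w": 1.0,
  "alpha": 1.0, "alpha_bar": 1.0, "beta": 1.0, "beta_bar": 1.0
}
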