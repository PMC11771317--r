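{
  "kBC0": 0.0, "kBC_Ca2": 1.9453, "kCB0": 2.3617, "kCB_Ca2": 0.3939,
  "fCM1_0": 42.9689, "fM1C_0": 50.2944,
  "kM1M2": 42.5863, "kM2M1": 44.7155, "kM2C": 47.8151,
  "pCa50": 5.64,
  "u1": 1.0054, "u2": 2.2659, "z1": 1.0047, "z2": 1.0118, "v": 1.0067, "w": 1.0463,
  "alpha": 0.9996, "alpha_bar": 0.8897, "beta": 0.9466, "beta_bar": 0.1376
}
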