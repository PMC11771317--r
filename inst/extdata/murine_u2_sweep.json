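{ "species": "murine", "base_set": 8, "vary": "u2",
  "values": [2.2659, 4.0, 7.0, 10.0], "pCa": [6.1, 4.5] }
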