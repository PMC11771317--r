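{ "species": "murine", "base_set": 8, "vary": "z2",
  "values": [1.50, 2.00], "pCa": [6.1, 4.5] }
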