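{ "species": "porcine", "base_set": 8, "vary": "u2",
  "values": [17.082, 16.0, 13.0, 10.0], "pCa": [6.1, 4.5] }
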