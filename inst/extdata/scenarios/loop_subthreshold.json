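{
  "provenance": "sub-threshold template whose homeostatic loop develops a spontaneous discharge",
  "x": {"gmax": 0, "p": 1, "V_half": -60, "k": 5, "tau": 5, "E_X": 50},
  "noise": {"enabled": false}
}
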