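{
  "provenance": "instantaneous-activation variant of the standard sodium template",
  "x": {"gmax": 0, "p": 1, "V_half": -45, "k": 5, "tau": "instantaneous", "E_X": 50}
}
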