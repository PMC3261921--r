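{
  "provenance": "slowly inactivating sub-threshold sodium-type variant",
  "x": {"gmax": 0, "p": 1, "V_half": -60, "k": 6, "tau": 5, "E_X": 50,
        "inactivation": {"V_half": -60, "k": 6, "tau": 20}}
}
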