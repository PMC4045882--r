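{
  "id": "urea_B_synthetic",
  "reactions": [
    {"id": "R01398", "inputs": ["C00077", "C00169"],
     "outputs": ["C00327", "C00009"], "ec": ["2.1.3.3"],
     "reversible": false},
    {"id": "R01954", "inputs": ["C00327", "C00049", "C00002"],
     "outputs": ["C03406", "C00020", "C00013"], "ec": ["6.3.4.5"],
     "reversible": false},
    {"id": "R01086", "inputs": ["C03406"],
     "outputs": ["C00062", "C00122"], "ec": ["4.3.2.1"],
     "reversible": false},
    {"id": "R02282", "inputs": ["C00062"],
     "outputs": ["C03771"], "ec": ["2.6.1.84"],
     "reversible": false}
  ]
}
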