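{
  "id": "urea_A_synthetic",
  "reactions": [
    {"id": "R00551", "inputs": ["C00062", "C00001"],
     "outputs": ["C00086", "C00077"], "ec": ["3.5.3.1"],
     "reversible": false},
    {"id": "R01398", "inputs": ["C00077", "C00169"],
     "outputs": ["C00327", "C00009"], "ec": ["2.1.3.3"],
     "reversible": false},
    {"id": "R01954", "inputs": ["C00327", "C00049", "C00002"],
     "outputs": ["C03406", "C00020", "C00013"], "ec": ["6.3.4.5"],
     "reversible": false},
    {"id": "R01086", "inputs": ["C03406"],
     "outputs": ["C00062", "C00122"], "ec": ["4.3.2.1"],
     "reversible": false},
    {"id": "R00557", "inputs": ["C00327"],
     "outputs": ["C00438"], "ec": ["3.5.1.20"],
     "reversible": true}
  ]
}
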