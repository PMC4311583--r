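{
  "CMC": "factor",
  "Sucrose": "factor",
  "YeastExtract": "factor",
  "Peptone": "factor",
  "K2HPO4": "factor",
  "MgSO4": "factor",
  "Temperature": "factor",
  "pH": "factor",
  "D1": "dummy",
  "D2": "dummy",
  "D3": "dummy"
}
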