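factor,low,high
CMC,0.1,1
Sucrose,0.02,0.2
YeastExtract,0.02,0.2
Peptone,0.05,0.5
K2HPO4,0.01,0.1
MgSO4,0.01,0.1
Temperature,28,37
pH,9,5
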