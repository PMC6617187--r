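{
  "risk": [0.05, 0.10],
  "le": [10, 15],
  "gain": [1, 2]
}
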