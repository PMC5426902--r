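{
  "experiment": "matrix",
  "model": "switch",
  "protocol": "subsample",
  "intervals": [1, 1.5, 2, 2.5, 3, 4],
  "spacings": [2, 3, 4, 5, 6, 8],
  "out_dir": "switch_reference_out"
}
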