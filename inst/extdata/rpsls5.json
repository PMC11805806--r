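{
  "A": [
    [-0.5, -1, 1, -1, 1],
    [1, -0.5, -1, 1, -1],
    [-1, 1, -0.5, -1, 1],
    [1, -1, 1, -0.5, -1],
    [-1, 1, -1, 1, -0.5]
  ],
  "b": [1, 1, 1, 1, 1],
  "labels": ["1", "2", "3", "4", "5"]
}
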