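{
  "names": ["hematoxylin", "DAB", "residual"],
  "vectors": [
    [0.650, 0.704, 0.286],
    [0.268, 0.570, 0.776],
    [0.6362142, -0.7100268, 0.3018168]
  ]
}
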