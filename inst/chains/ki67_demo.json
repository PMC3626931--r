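{
  "name": "ki67_demo",
  "steps": [
    {"step": "threshold_segment",
     "args": {"source": "stain_sum", "threshold": 0.15,
              "polarity": "above", "matrix": "hdab"}},
    {"step": "connected_components"},
    {"step": "remove_small", "args": {"min_area": 15}},
    {"step": "morphometry"},
    {"step": "stain_intensity", "args": {"matrix": "hdab"}},
    {"step": "rule",
     "args": {"feature": "area", "op": "ge", "t": 80,
              "true": "tumor", "false": "normal"}},
    {"step": "rule",
     "args": {"feature": "mean_DAB", "op": "ge", "t": 0.15,
              "true": "Ki67+", "false": "Ki67-", "scope": ["tumor"]}},
    {"step": "num_class"},
    {"step": "export", "args": {"file": "ki67_results.csv"}}
  ]
}
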