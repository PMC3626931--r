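{
  "name": "cell_interaction_demo",
  "steps": [
    {"step": "merge_channels",
     "args": {"specs": [
        {"channel": "B", "class": "bone", "priority": 0},
        {"channel": "G", "class": "osteoclast", "priority": 1},
        {"channel": "R", "class": "monocyte", "priority": 2}],
      "min_area": 20}},
    {"step": "voronoi"},
    {"step": "network"},
    {"step": "relational", "args": {"classes": ["bone"]}},
    {"step": "interacting",
     "args": {"source": "osteoclast", "target": "bone",
              "as": "osteoclast interacting"}},
    {"step": "num_class"},
    {"step": "export", "args": {"file": "interaction_results.csv"}}
  ]
}
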