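{
  "schema_version": "1.0",
  "kind": "prototype_problem",
  "universe": ["x1", "x2", "x3"],
  "prototypes": {
    "P1": {
      "mu": ["1", "0.6", "0.4"],
      "nu": ["0", "0.2", "0.3"]
    },
    "P2": {
      "mu": ["0.7", "1", "0.2"],
      "nu": ["0.1", "0", "0.6"]
    },
    "P3": {
      "mu": ["0.8", "0.5", "0.9"],
      "nu": ["0.1", "0.1", "0"]
    }
  },
  "query": {
    "mu": ["0.6", "0.9", "0.1"],
    "nu": ["0.2", "0.1", "0.7"]
  }
}
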