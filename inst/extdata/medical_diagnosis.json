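{
  "schema_version": "1.0",
  "kind": "prototype_problem",
  "universe": ["headache", "cough", "chest_pain", "temperature", "stomach_pain"],
  "prototypes": {
    "P1 (Malaria)": {
      "mu": ["0.7", "0.5", "0.2", "0.5", "0.3"],
      "nu": ["0.1", "0.5", "0.8", "0.3", "0.7"]
    },
    "P2 (Kidney Stone)": {
      "mu": ["0.1", "0.9", "0.5", "0.7", "0.8"],
      "nu": ["0.4", "0", "0.2", "0.1", "0.1"]
    },
    "P3 (Typhoid)": {
      "mu": ["0.2", "1", "0.6", "0.1", "0.3"],
      "nu": ["0.7", "0", "0.3", "0.9", "0.4"]
    },
    "P4 (Dengue)": {
      "mu": ["0.6", "0.7", "0.5", "0.2", "0.7"],
      "nu": ["0.1", "0.2", "0.4", "0.3", "0.3"]
    },
    "P5 (Viral Fever)": {
      "mu": ["0.9", "0.1", "0.4", "0.1", "0.8"],
      "nu": ["0", "0.2", "0.4", "0.2", "0.2"]
    }
  },
  "query": {
    "mu": ["0.8", "0.4", "0.1", "0.5", "0.2"],
    "nu": ["0.2", "0.4", "0.8", "0.4", "0.6"]
  }
}
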