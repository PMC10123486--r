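{
  "schema_version": "1.0",
  "kind": "decision_problem",
  "criteria": ["C1", "C2", "C3", "C4", "C5", "C6", "C7", "C8"],
  "polarity": {
    "C1": "cost",
    "C2": "cost",
    "C3": "cost",
    "C4": "cost",
    "C5": "cost",
    "C6": "benefit",
    "C7": "benefit",
    "C8": "benefit"
  },
  "alternatives": {
    "M1": {
      "mu": ["0.2", "0.2", "0.4", "0.5", "0.5", "0.5", "0.1", "0.5"],
      "nu": ["0.7", "0.6", "0.7", "0.8", "0.6", "0.7", "0.7", "0.8"]
    },
    "M2": {
      "mu": ["0.4", "0.3", "0.1", "0.4", "0.7", "0.4", "0.4", "0.3"],
      "nu": ["0.7", "0.9", "0.8", "0.7", "0.7", "0.6", "0.8", "0.6"]
    },
    "M3": {
      "mu": ["0.2", "0.1", "0.2", "0.4", "0.6", "0.3", "0.2", "0.4"],
      "nu": ["0.9", "0.8", "0.7", "0.4", "0.7", "0.8", "0.9", "0.7"]
    },
    "M4": {
      "mu": ["0.1", "0.4", "0.4", "0.2", "0.3", "0.2", "0.3", "0.5"],
      "nu": ["0.7", "0.7", "0.8", "0.5", "0.7", "0.8", "0.7", "0.5"]
    },
    "M5": {
      "mu": ["0.1", "0.2", "0.3", "0.4", "0.1", "0.9", "0.8", "0.8"],
      "nu": ["0.6", "0.9", "0.8", "0.6", "0.8", "0.2", "0.3", "0.4"]
    },
    "M6": {
      "mu": ["0.3", "0.3", "0.4", "0.1", "0.4", "0.1", "0.2", "0.6"],
      "nu": ["0.8", "0.6", "0.9", "0.8", "0.7", "0.9", "0.8", "0.7"]
    }
  }
}
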