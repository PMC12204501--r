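{
  "edges": [
    {
      "from": "1",
      "prob": 1,
      "to": "2"
    },
    {
      "from": "2",
      "prob": 1,
      "to": "4"
    },
    {
      "from": "4",
      "prob": 0.37,
      "to": "7"
    },
    {
      "from": "4",
      "prob": 0.63,
      "to": "8"
    },
    {
      "from": "7",
      "prob": 1,
      "to": "x7"
    },
    {
      "from": "8",
      "prob": 1,
      "to": "x8"
    }
  ],
  "meta": {
    "prevalence": 0.1665,
    "scenario": "scenario-4"
  },
  "nodes": {
    "1": {
      "actor": "human",
      "cost": 0,
      "id": "1",
      "kind": "action",
      "label": "clinical intake",
      "tat": 0
    },
    "2": {
      "actor": "human",
      "cost": 165,
      "id": "2",
      "kind": "decision",
      "label": "Decision 1",
      "tat": 4
    },
    "4": {
      "actor": "human",
      "cost": 4589.4,
      "id": "4",
      "kind": "action",
      "label": "ES (first tier)",
      "tat": 8
    },
    "7": {
      "actor": "human",
      "cost": 0,
      "id": "7",
      "kind": "result",
      "label": "ES positive",
      "result_value": "positive",
      "tat": 0,
      "test_ref": "es"
    },
    "8": {
      "actor": "human",
      "cost": 0,
      "id": "8",
      "kind": "result",
      "label": "ES negative",
      "result_value": "negative",
      "tat": 0,
      "test_ref": "es"
    },
    "x7": {
      "actor": "human",
      "cost": 0,
      "id": "x7",
      "kind": "exit",
      "label": "exit: ES diagnosis",
      "tat": 0
    },
    "x8": {
      "actor": "human",
      "cost": 0,
      "id": "x8",
      "kind": "exit",
      "label": "exit: undiagnosed",
      "tat": 0
    }
  },
  "root": "1",
  "tests": {
    "cma": {
      "se": 0.9068,
      "sp": 0.944
    },
    "es": {
      "se": 0.9593,
      "sp": 0.9933
    },
    "gp": {
      "se": 0.896,
      "sp": 0.925
    }
  }
}
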