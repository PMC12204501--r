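{
  "edges": [
    {
      "from": "1",
      "prob": 1,
      "to": "2"
    },
    {
      "from": "10",
      "prob": 1,
      "to": "13"
    },
    {
      "from": "13",
      "prob": 0.35,
      "to": "15"
    },
    {
      "from": "13",
      "prob": 0.65,
      "to": "16"
    },
    {
      "from": "15",
      "prob": 1,
      "to": "x15"
    },
    {
      "from": "16",
      "prob": 1,
      "to": "x16"
    },
    {
      "from": "2",
      "prob": 1,
      "to": "3"
    },
    {
      "from": "3",
      "prob": 0.1,
      "to": "5"
    },
    {
      "from": "3",
      "prob": 0.9,
      "to": "6"
    },
    {
      "from": "5",
      "prob": 1,
      "to": "x5"
    },
    {
      "from": "6",
      "prob": 1,
      "to": "10"
    }
  ],
  "meta": {
    "prevalence": 0.1665,
    "scenario": "scenario-3"
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
    "10": {
      "actor": "human",
      "cost": 165,
      "id": "10",
      "kind": "decision",
      "label": "Decision 2",
      "tat": 4
    },
    "13": {
      "actor": "human",
      "cost": 4589.4,
      "id": "13",
      "kind": "action",
      "label": "ES (second tier)",
      "tat": 8
    },
    "15": {
      "actor": "human",
      "cost": 0,
      "id": "15",
      "kind": "result",
      "label": "ES positive",
      "result_value": "positive",
      "tat": 0,
      "test_ref": "es"
    },
    "16": {
      "actor": "human",
      "cost": 0,
      "id": "16",
      "kind": "result",
      "label": "ES negative",
      "result_value": "negative",
      "tat": 0,
      "test_ref": "es"
    },
    "2": {
      "actor": "human",
      "cost": 165,
      "id": "2",
      "kind": "decision",
      "label": "Decision 1",
      "tat": 4
    },
    "3": {
      "actor": "human",
      "cost": 825,
      "id": "3",
      "kind": "action",
      "label": "CMA",
      "tat": 2
    },
    "5": {
      "actor": "human",
      "cost": 0,
      "id": "5",
      "kind": "result",
      "label": "CMA positive",
      "result_value": "positive",
      "tat": 0,
      "test_ref": "cma"
    },
    "6": {
      "actor": "human",
      "cost": 0,
      "id": "6",
      "kind": "result",
      "label": "CMA negative",
      "result_value": "negative",
      "tat": 0,
      "test_ref": "cma"
    },
    "x15": {
      "actor": "human",
      "cost": 0,
      "id": "x15",
      "kind": "exit",
      "label": "exit: ES diagnosis",
      "tat": 0
    },
    "x16": {
      "actor": "human",
      "cost": 0,
      "id": "x16",
      "kind": "exit",
      "label": "exit: undiagnosed",
      "tat": 0
    },
    "x5": {
      "actor": "human",
      "cost": 0,
      "id": "x5",
      "kind": "exit",
      "label": "exit: CMA diagnosis",
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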