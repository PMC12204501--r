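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
      "to": "14"
    },
    {
      "from": "14",
      "prob": 0.11,
      "to": "17"
    },
    {
      "from": "14",
      "prob": 0.89,
      "to": "18"
    },
    {
      "from": "17",
      "prob": 1,
      "to": "x17"
    },
    {
      "from": "18",
      "prob": 1,
      "to": "22"
    },
    {
      "from": "2",
      "prob": 1,
      "to": "3"
    },
    {
      "from": "22",
      "prob": 1,
      "to": "24"
    },
    {
      "from": "24",
      "prob": 0.33,
      "to": "25"
    },
    {
      "from": "24",
      "prob": 0.67,
      "to": "26"
    },
    {
      "from": "25",
      "prob": 1,
      "to": "x25"
    },
    {
      "from": "26",
      "prob": 1,
      "to": "x26"
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
    "scenario": "scenario-2"
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
    "14": {
      "actor": "human",
      "cost": 1500,
      "id": "14",
      "kind": "action",
      "label": "gene panel",
      "tat": 4
    },
    "17": {
      "actor": "human",
      "cost": 0,
      "id": "17",
      "kind": "result",
      "label": "GP positive",
      "result_value": "positive",
      "tat": 0,
      "test_ref": "gp"
    },
    "18": {
      "actor": "human",
      "cost": 0,
      "id": "18",
      "kind": "result",
      "label": "GP negative",
      "result_value": "negative",
      "tat": 0,
      "test_ref": "gp"
    },
    "2": {
      "actor": "human",
      "cost": 165,
      "id": "2",
      "kind": "decision",
      "label": "Decision 1",
      "tat": 4
    },
    "22": {
      "actor": "human",
      "cost": 165,
      "id": "22",
      "kind": "decision",
      "label": "Decision 3",
      "tat": 4
    },
    "24": {
      "actor": "human",
      "cost": 4589.4,
      "id": "24",
      "kind": "action",
      "label": "ES (third tier)",
      "tat": 8
    },
    "25": {
      "actor": "human",
      "cost": 0,
      "id": "25",
      "kind": "result",
      "label": "ES positive",
      "result_value": "positive",
      "tat": 0,
      "test_ref": "es"
    },
    "26": {
      "actor": "human",
      "cost": 0,
      "id": "26",
      "kind": "result",
      "label": "ES negative",
      "result_value": "negative",
      "tat": 0,
      "test_ref": "es"
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
    "x17": {
      "actor": "human",
      "cost": 0,
      "id": "x17",
      "kind": "exit",
      "label": "exit: GP diagnosis",
      "tat": 0
    },
    "x25": {
      "actor": "human",
      "cost": 0,
      "id": "x25",
      "kind": "exit",
      "label": "exit: ES diagnosis",
      "tat": 0
    },
    "x26": {
      "actor": "human",
      "cost": 0,
      "id": "x26",
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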