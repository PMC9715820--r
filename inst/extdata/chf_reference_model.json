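{
  "description": "Reference five-state cycle model for a chronic heart-failure service population assessed at 4-month intervals, transcribed from an external clinical analysis. Transition probabilities are quoted to 2 decimal places. The OPD-to-Left entry of R is stored as null: the quoted value (0.18) breaks the unit row sum (1.09) and is completed by the unit-row-sum complement (0.09) on load; the repair is disclosed in the model's repair log. Observed per-cycle distributions are quoted for cycles 1-5 only (the quoted cycle-6 row is incomplete).",
  "states": ["D", "L", "H", "O", "N"],
  "R": [[0.07, 0.17], [0.02, null], [0.05, 0.0]],
  "Q": [[0.24, 0.14, 0.38], [0.12, 0.22, 0.55], [0.19, 0.13, 0.63]],
  "first_transition_counts": {"D": 427, "L": 1842, "H": 1559, "O": 2254, "N": 1414},
  "observed": {
    "cycle": [1, 2, 3, 4, 5],
    "D": [0.06, 0.09, 0.11, 0.14, 0.16],
    "L": [0.25, 0.31, 0.34, 0.41, 0.47],
    "H": [0.21, 0.12, 0.11, 0.10, 0.10],
    "O": [0.30, 0.12, 0.26, 0.15, 0.07],
    "N": [0.19, 0.36, 0.18, 0.21, 0.20]
  }
}
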