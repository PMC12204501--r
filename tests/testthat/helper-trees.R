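# Small trees and independent oracles shared across the test files.

# decision(165) -> action(825) -> {positive 0.1 -> exit, negative 0.9 ->
# decision(165) -> exit}; hand-enumerated paths: (p=0.1, cost=990) and
# (p=0.9, cost=1155), so the expected cost is 1138.5.
oracle_tree <- function(cost_scale = 1) {
  dx_tree(
    list(dx_node("d1", "decision", cost = 165 * cost_scale, tat = 4),
         dx_node("a1", "action", cost = 825 * cost_scale, tat = 2),
         dx_node("rp", "result", result_value = "positive", test_ref = "t"),
         dx_node("rn", "result", result_value = "negative", test_ref = "t"),
         dx_node("x1", "exit"),
         dx_node("d2", "decision", cost = 165 * cost_scale, tat = 4),
         dx_node("x2", "exit")),
    data.frame(from = c("d1", "a1", "a1", "rp", "rn", "d2"),
               to = c("a1", "rp", "rn", "x1", "d2", "x2"),
               prob = c(1, 0.1, 0.9, 1, 1, 1)),
    tests = list(t = list(se = 0.9, sp = 0.9)))
}

# independent recomputation of one path's attribute total by a plain walk
naive_path_sum <- function(tree, node_ids, attribute) {
  sum(vapply(node_ids, function(id) tree$nodes[[id]][[attribute]],
             numeric(1)))
}

# brute-force predictive values from an expected 2x2 contingency table
contingency_pv <- function(se, sp, p, N = 1e6) {
  tp <- N * p * se
  fn <- N * p * (1 - se)
  tn <- N * (1 - p) * sp
  fp <- N * (1 - p) * (1 - sp)
  list(ppv = tp / (tp + fp), npv = tn / (tn + fn))
}

# expected value over enumerated paths -- the enumeration oracle for the
# leaf-to-root recursion
path_expectation <- function(tree, attribute = "cost") {
  paths <- enumerate_paths(tree)
  sum(paths$prob * paths[[attribute]])
}

minimal_doc <- function() {
  '{
    "root": "d",
    "nodes": [
      {"id": "d", "kind": "decision"},
      {"id": "a", "kind": "action", "cost": 10},
      {"id": "rp", "kind": "result", "result_value": "positive"},
      {"id": "rn", "kind": "result", "result_value": "negative"},
      {"id": "x1", "kind": "exit"},
      {"id": "x2", "kind": "exit"}
    ],
    "edges": [
      {"from": "d", "to": "a", "prob": 1},
      {"from": "a", "to": "rp", "prob": 0.25},
      {"from": "a", "to": "rn", "prob": 0.75},
      {"from": "rp", "to": "x1", "prob": 1},
      {"from": "rn", "to": "x2", "prob": 1}
    ]
  }'
}
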