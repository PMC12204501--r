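test_that("ai_config enforces its invariants", {
  expect_error(ai_config(precision = 1.2), "\\[0,1\\]")
  expect_error(ai_config(0.8, gate_prob = 0.5, mode = "patient"),
               "exactly 0 or 1")
  expect_silent(ai_config(0.8, gate_prob = 1, mode = "patient"))
  probs <- ai_transition_probabilities(ai_config(0.87, gate_prob = 0.6))
  expect_equal(probs$gate, 0.6)
  expect_equal(probs$non_gate, 0.4)
  expect_equal(probs$automated_positive, 0.87)
  expect_equal(probs$automated_negative, 0.13)
  expect_equal(ai_transition_probabilities(ai_config(0.9, gate_prob = 1))$non_gate, 0)
})

test_that("delegation preserves normalization and rewires the decision", {
  tr <- build_ai_tree(ai = ai_config(precision = 0.87, gate_prob = 0.7))
  expect_equal(nrow(validate_tree(tr)), 0)
  # gate probabilities on the AI result nodes
  e <- tr$edges
  expect_equal(e$prob[e$from == "1'" & e$to == "2'"], 0.7)
  expect_equal(e$prob[e$from == "1'" & e$to == "3'"], 0.3)
  # automated panel yield is the AI precision
  expect_equal(e$prob[e$from == "14'" & e$to == "17'"], 0.87)
  # automated-branch decisions carry no fee, fallback decision keeps it
  expect_equal(tr$nodes[["22'"]]$cost, 0)
  expect_equal(tr$nodes[["22'"]]$actor, "ai")
  expect_equal(tr$nodes[["10"]]$cost, 165)
  expect_equal(sum(enumerate_paths(tr)$prob), 1, tolerance = 1e-9)
})

test_that("delegate rejects bad anchors and degenerate structures", {
  base <- build_scenario(2)
  fb <- build_scenario(3)
  expect_error(delegate(base, "3", ai_config(0.8), "14", fb),
               "not a decision node")
  expect_error(delegate(base, "10", ai_config(0.8), "24", fb),
               "not a candidate action")
})

test_that("a closed gate reduces to the fallback pathway", {
  p <- case_params()
  shut <- build_ai_tree(p, ai_config(precision = 0.87, gate_prob = 0))
  s3 <- build_scenario(3, p)
  cr_ai <- expected_cost(shut)
  cr_s3 <- expected_cost(s3)
  expect_equal(cr_ai$expected_cost, cr_s3$expected_cost, tolerance = 1e-9)
  expect_equal(cr_ai$expected_tat, cr_s3$expected_tat, tolerance = 1e-9)
  up <- case_utility(p)
  expect_equal(effective_cost(shut, up), effective_cost(s3, up),
               tolerance = 1e-9)
})

test_that("an open gate saves exactly the automated decision fees", {
  p <- case_params()
  s2_cost <- expected_cost(build_scenario(2, p))$expected_cost
  # the skipped post-CMA decision is reached with probability 0.9 and the
  # automated third-tier review with probability 0.9 * (1 - precision)
  pr <- p$yield_gp  # precision equal to the expert-mode panel yield
  open <- build_ai_tree(p, ai_config(precision = pr, gate_prob = 1))
  oracle <- path_expectation(open, "cost")
  expect_equal(expected_cost(open)$expected_cost, oracle, tolerance = 1e-9)
  expect_equal(oracle,
               s2_cost - 0.9 * p$expert_fee - 0.9 * (1 - pr) * p$expert_fee,
               tolerance = 1e-9)
  # keeping expert review on the automated branch saves only the gate fee
  fb <- dx_tree(lapply(c("10", "13", "15", "16", "x15", "x16"), function(id) {
    if (id == "10") dx_node("10", "decision", cost = p$expert_fee,
                            tat = p$tat_expert)
    else if (id == "13") dx_node("13", "action", cost = p$cost_es,
                                 tat = p$tat_es)
    else if (id == "15") dx_node("15", "result", result_value = "positive",
                                 test_ref = "es")
    else if (id == "16") dx_node("16", "result", result_value = "negative",
                                 test_ref = "es")
    else dx_node(id, "exit")
  }),
  data.frame(from = c("10", "13", "13", "15", "16"),
             to = c("13", "15", "16", "x15", "x16"),
             prob = c(1, p$yield_es_tier2, 1 - p$yield_es_tier2, 1, 1)),
  root = "10", tests = list(es = list(se = p$se_es, sp = p$sp_es)))
  kept <- delegate(build_scenario(2, p), "10",
                   ai_config(precision = pr, gate_prob = 1), "14", fb,
                   automate_branch = FALSE)
  expect_equal(expected_cost(kept)$expected_cost,
               s2_cost - 0.9 * p$expert_fee, tolerance = 1e-9)
})

test_that("effective cost falls monotonically with AI precision", {
  up <- case_utility()
  grid <- seq(0.05, 1, by = 0.05)
  vals <- vapply(grid, function(pr)
    effective_cost(build_ai_tree(ai = ai_config(precision = pr)), up),
    numeric(1))
  expect_true(all(diff(vals) < 0))
})

test_that("crossover bisection agrees with a dense grid scan", {
  x <- case_crossover(alpha = 0.5, tol = 1e-4)
  expect_identical(attr(x, "status"), "found")
  p <- case_params()
  up <- case_utility(p)
  target <- min(effective_cost(build_scenario(2, p), up),
                effective_cost(build_scenario(3, p), up))
  grid <- seq(0.40, 0.43, by = 1e-4)
  ok <- vapply(grid, function(pr)
    effective_cost(build_ai_tree(p, ai_config(precision = pr)), up) <= target,
    logical(1))
  expect_true(any(ok))
  oracle <- grid[which(ok)[1]]
  expect_lt(abs(as.numeric(x) - oracle), 2e-4)
})

test_that("crossover reports 'never' when even perfect precision loses", {
  p <- case_params()
  up <- case_utility(p)
  builder <- function(pr) build_ai_tree(p, ai_config(precision = pr))
  res <- crossover_precision(builder, list(build_scenario(1, p)), up)
  expect_identical(attr(res, "status"), "never")
  expect_true(is.na(as.numeric(res)))
})

test_that("a non-monotone objective aborts the bisection with advice", {
  p <- case_params()
  up <- case_utility(p)
  # abuse the builder: precision inflates the CMA cost, so the effective
  # cost of the 'AI' tree rises along the grid
  builder <- function(pr)
    build_scenario(1, case_params(cost_cma = 825 + 4000 * pr))
  expect_error(crossover_precision(builder, list(build_scenario(4, p)), up),
               "monotone")
})

test_that("delegation beats both multi-tier expert baselines at high precision", {
  p <- case_params()
  for (alpha in seq(0.1, 0.9, by = 0.2)) {
    up <- case_utility(p, alpha = alpha)
    ai_ec <- effective_cost(build_ai_tree(p, ai_config(precision = 0.87)), up)
    expect_lt(ai_ec, effective_cost(build_scenario(2, p), up))
    expect_lt(ai_ec, effective_cost(build_scenario(3, p), up))
  }
})
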