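test_that("predictive values match the contingency-table brute force", {
  grid <- expand.grid(se = seq(0.05, 0.95, length.out = 10),
                      sp = seq(0.05, 0.95, length.out = 10),
                      p = seq(0.05, 0.95, length.out = 10))
  for (i in seq_len(nrow(grid))) {
    o <- contingency_pv(grid$se[i], grid$sp[i], grid$p[i])
    expect_equal(ppv(grid$se[i], grid$sp[i], grid$p[i]), o$ppv,
                 tolerance = 1e-9)
    expect_equal(npv(grid$se[i], grid$sp[i], grid$p[i]), o$npv,
                 tolerance = 1e-9)
  }
})

test_that("predictive values honour their boundary identities", {
  expect_equal(ppv(0.9, 0.9, 1), 1)          # everyone diseased
  expect_equal(ppv(0.42, 1, 0.3), 1)         # no false positives
  expect_equal(npv(0.3, 0.8, 0), 1)          # nobody diseased
  expect_equal(npv(1, 0.6, 0.4), 1)          # no false negatives
  expect_error(ppv(0, 1, 0.5), "positive")   # no predicted positives
  expect_error(npv(1, 0, 0.5), "negative")
  expect_error(ppv(1.2, 0.5, 0.5), "\\[0,1\\]")
})

test_that("case-study predictive values take their expected values", {
  # CMA performance at the case-study prevalence, against the brute force
  o <- contingency_pv(0.9068, 0.9440, 0.1665)
  expect_equal(ppv(0.9068, 0.9440, 0.1665), o$ppv, tolerance = 1e-12)
  expect_equal(npv(0.9068, 0.9440, 0.1665), o$npv, tolerance = 1e-12)
  expect_equal(round(o$ppv, 4), 0.7639)
  expect_equal(round(o$npv, 4), 0.9807)
})

test_that("posterior after a negative complements the NPV", {
  expect_equal(posterior_after_negative(0.3, 1, 0.7), 0)   # negative rules out
  expect_equal(posterior_after_negative(0.3, 0, 1), 0.3)   # uninformative
  for (se in c(0.2, 0.7, 0.95)) for (sp in c(0.3, 0.8, 0.99))
    for (p in c(0.01, 0.1665, 0.6)) {
      expect_equal(posterior_after_negative(p, se, sp), 1 - npv(se, sp, p),
                   tolerance = 1e-12)
    }
  expect_equal(round(posterior_after_negative(0.1665, 0.9068, 0.9440), 4),
               0.0193)
})

test_that("expected gain in utility weighs outcomes by predictive values", {
  up <- utility_params(prevalence = 0.2)
  expect_equal(expected_gain_utility("positive", ppv = 1, params = up), 1)
  expect_equal(expected_gain_utility("positive", ppv = 0.5, params = up), 0)
  # symmetric utilities collapse to 2*NPV - 1
  expect_equal(expected_gain_utility("negative", npv = 0.9807, params = up),
               2 * 0.9807 - 1)
  expect_equal(expected_gain_utility("none", params = up), 0)
  up2 <- utility_params(prevalence = 0.2, no_result_egu = 0.25)
  expect_equal(expected_gain_utility("none", params = up2), 0.25)
})

test_that("outcome utility blends accuracy and delay as specified", {
  up <- function(alpha, lambda = 0.03)
    utility_params(prevalence = 0.1665, alpha = alpha, lambda = lambda)
  expect_equal(outcome_utility(0.5278, 99, up(1)), 0.5278)  # accuracy-only
  expect_equal(outcome_utility(0.3, 0, up(0)), 1)           # e^0
  expect_equal(outcome_utility(0.5278, 6, up(0.5)),
               0.5 * 0.5278 + 0.5 * exp(-0.03 * 6))
  expect_equal(round(outcome_utility(0.5278, 6, up(0.5)), 4), 0.6815)
  # non-increasing in delay, linear in gain at fixed delay
  u <- outcome_utility(0.4, 0:20, up(0.5))
  expect_true(all(diff(u) <= 0))
  expect_equal(outcome_utility(0.8, 5, up(0.3)) -
                 outcome_utility(0.2, 5, up(0.3)), 0.3 * 0.6)
  expect_error(outcome_utility(0.5, -1, up(0.5)), ">= 0")
})

test_that("expected effectiveness reduces to known closed forms", {
  # single positive pathway with a perfect test and alpha = 1
  tr <- dx_tree(list(dx_node("a", "action"),
                     dx_node("rp", "result", result_value = "positive",
                             test_ref = "t", terminal = TRUE)),
                data.frame(from = "a", to = "rp", prob = 1),
                tests = list(t = list(se = 0.5, sp = 1)))
  up <- utility_params(prevalence = 0.3, alpha = 1)
  expect_equal(expected_effectiveness(tr, up)$expected_effectiveness, 1)

  # two equiprobable resultless pathways with opposite gains cancel
  tr2 <- dx_tree(list(dx_node("a", "action"),
                      dx_node("x1", "exit"), dx_node("x2", "exit")),
                 data.frame(from = c("a", "a"), to = c("x1", "x2"),
                            prob = c(0.5, 0.5)))
  up_pos <- utility_params(prevalence = 0.3, alpha = 1, no_result_egu = 0.4)
  eff <- expected_effectiveness(tr2, up_pos)$expected_effectiveness
  expect_equal(eff, 0.4)  # both pathways earn the same neutral gain
  up0 <- utility_params(prevalence = 0.3, alpha = 1)
  expect_equal(expected_effectiveness(tr2, up0)$expected_effectiveness, 0)
})

test_that("per-path report is internally consistent", {
  up <- case_utility()
  rep <- expected_effectiveness(build_scenario(2), up)
  expect_equal(rep$expected_effectiveness,
               sum(rep$per_path$prob * rep$per_path$utility),
               tolerance = 1e-9)
})

test_that("scenario-1 effectiveness equals a path-by-path hand enumeration", {
  p <- case_params()
  up <- case_utility(p, alpha = 0.5, lambda = 0.03)
  # the three pathways: CMA+, GP+, GP- (undiagnosed exit after review)
  pv_cma <- contingency_pv(p$se_cma, p$sp_cma, p$prevalence)
  pv_gp <- contingency_pv(p$se_gp, p$sp_gp, p$prevalence)
  hand <- 0.1 * (0.5 * (2 * pv_cma$ppv - 1) + 0.5 * exp(-0.03 * 6)) +
    0.9 * 0.11 * (0.5 * (2 * pv_gp$ppv - 1) + 0.5 * exp(-0.03 * 14)) +
    0.9 * 0.89 * (0.5 * (2 * pv_gp$npv - 1) + 0.5 * exp(-0.03 * 18))
  got <- expected_effectiveness(build_scenario(1), up)$expected_effectiveness
  expect_equal(got, hand, tolerance = 1e-12)
})

test_that("serial Bayes mode chains the prevalence through prior negatives", {
  p <- case_params()
  up <- case_utility(p, pv_mode = "serial_bayes")
  rep <- expected_effectiveness(build_scenario(3), up)
  per <- rep$per_path
  # the second-tier ES pathways should use the post-CMA-negative prevalence
  p_post <- posterior_after_negative(p$prevalence, p$se_cma, p$sp_cma)
  pv_es <- contingency_pv(p$se_es, p$sp_es, p_post)
  es_pos <- per[per$final_test == "es" & per$final_result == "positive", ]
  expect_equal(es_pos$egu, 2 * pv_es$ppv - 1, tolerance = 1e-12)
  es_neg <- per[per$final_test == "es" & per$final_result == "negative", ]
  expect_equal(es_neg$egu, 2 * pv_es$npv - 1, tolerance = 1e-12)
  # the first-tier CMA-positive pathway still uses the baseline prevalence
  cma_pos <- per[per$final_test == "cma", ]
  expect_equal(cma_pos$egu,
               2 * contingency_pv(p$se_cma, p$sp_cma, p$prevalence)$ppv - 1,
               tolerance = 1e-12)
})

test_that("effective cost is the cost/effectiveness ratio and scales with cost", {
  up <- case_utility()
  tr <- build_scenario(1)
  rep <- cost_effectiveness(tr, up)
  expect_equal(rep$effective_cost,
               rep$expected_cost / rep$expected_effectiveness)
  # doubling every node cost doubles effective cost, effectiveness unchanged
  tr2 <- tr
  for (id in names(tr2$nodes)) tr2$nodes[[id]]$cost <- 2 * tr2$nodes[[id]]$cost
  rep2 <- cost_effectiveness(tr2, up)
  expect_equal(rep2$expected_effectiveness, rep$expected_effectiveness)
  expect_equal(rep2$effective_cost, 2 * rep$effective_cost, tolerance = 1e-9)
})

test_that("non-positive effectiveness raises an explicit error", {
  tr <- dx_tree(list(dx_node("a", "action", cost = 100),
                     dx_node("rp", "result", result_value = "positive",
                             test_ref = "t", terminal = TRUE)),
                data.frame(from = "a", to = "rp", prob = 1),
                tests = list(t = list(se = 0.5, sp = 0.5)))
  up <- utility_params(prevalence = 0.01, alpha = 1)  # PPV ~ 0.01, EGU < 0
  expect_error(effective_cost(tr, up), "not positive")
})

test_that("a terminal result without a test reference is rejected", {
  tr <- dx_tree(list(dx_node("a", "action"),
                     dx_node("rp", "result", result_value = "positive",
                             terminal = TRUE)),
                data.frame(from = "a", to = "rp", prob = 1))
  expect_error(expected_effectiveness(tr, utility_params(prevalence = 0.2)),
               "test_ref")
})
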