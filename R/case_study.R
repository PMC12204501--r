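#' Case-study parameter registry: tiered genetic testing for DD & MCA
#'
#' Point parameters for the bundled case study of diagnostic strategies for
#' developmental delay and multiple congenital anomalies (DD & MCA):
#' chromosomal microarray (CMA), targeted gene panel (GP) and exome
#' sequencing (ES) arranged in up to three tiers, with an expert
#' consultation fee at every human decision point.  Diagnostic yields are
#' tier-specific marginal yields (the fraction of all tested individuals
#' with a positive result at that tier); sensitivities and specificities
#' feed predictive values; costs are US dollars and turnaround times weeks.
#'
#' @param expert_fee Expert consultation fee per human decision node.
#' @param cost_cma,cost_gp,cost_es Test costs.
#' @param tat_cma,tat_gp,tat_es,tat_expert,tat_ai Turnaround times (weeks).
#' @param yield_cma First-tier CMA diagnostic yield.
#' @param yield_gp Second-tier GP yield (after a negative CMA).
#' @param yield_es_tier1,yield_es_tier2,yield_es_tier3 ES yield when used
#'   as first, second or third tier.
#' @param se_cma,sp_cma,se_gp,sp_gp,se_es,sp_es Test sensitivities and
#'   specificities.
#' @param prevalence DD & MCA prevalence.
#' @param ai_precision Reference AI precision.
#' @return An object of class `dx_case_params` (named list).
#' @export
case_params <- function(expert_fee = 165,
                        cost_cma = 825, cost_gp = 1500, cost_es = 4589.4,
                        tat_cma = 2, tat_gp = 4, tat_es = 8,
                        tat_expert = 4, tat_ai = 0,
                        yield_cma = 0.1, yield_gp = 0.11,
                        yield_es_tier1 = 0.37, yield_es_tier2 = 0.35,
                        yield_es_tier3 = 0.33,
                        se_cma = 0.9068, sp_cma = 0.9440,
                        se_gp = 0.8960, sp_gp = 0.9250,
                        se_es = 0.9593, sp_es = 0.9933,
                        prevalence = 0.1665, ai_precision = 0.87) {
  p <- list(expert_fee = expert_fee, cost_cma = cost_cma, cost_gp = cost_gp,
            cost_es = cost_es, tat_cma = tat_cma, tat_gp = tat_gp,
            tat_es = tat_es, tat_expert = tat_expert, tat_ai = tat_ai,
            yield_cma = yield_cma, yield_gp = yield_gp,
            yield_es_tier1 = yield_es_tier1, yield_es_tier2 = yield_es_tier2,
            yield_es_tier3 = yield_es_tier3,
            se_cma = se_cma, sp_cma = sp_cma, se_gp = se_gp, sp_gp = sp_gp,
            se_es = se_es, sp_es = sp_es,
            prevalence = prevalence, ai_precision = ai_precision)
  probs <- c("yield_cma", "yield_gp", "yield_es_tier1", "yield_es_tier2",
             "yield_es_tier3", "se_cma", "sp_cma", "se_gp", "sp_gp",
             "se_es", "sp_es", "prevalence", "ai_precision")
  for (nm in probs)
    if (p[[nm]] < 0 || p[[nm]] > 1)
      stop("'", nm, "' must lie in [0,1]")
  for (nm in setdiff(names(p), probs))
    if (p[[nm]] < 0) stop("'", nm, "' must be >= 0")
  structure(p, class = "dx_case_params")
}

#' Utility parameters preconfigured for the case study
#'
#' @param params A [case_params()] registry (supplies the prevalence).
#' @param alpha,lambda Accuracy weight and delay decay rate.
#' @param ... Further arguments passed to [utility_params()].
#' @return A `dx_utility` object.
#' @export
case_utility <- function(params = case_params(), alpha = 0.5, lambda = 0.03,
                         ...) {
  utility_params(prevalence = params$prevalence, alpha = alpha,
                 lambda = lambda, ...)
}

.case_tests <- function(p) {
  list(cma = list(se = p$se_cma, sp = p$sp_cma),
       gp = list(se = p$se_gp, sp = p$sp_gp),
       es = list(se = p$se_es, sp = p$sp_es))
}

# intake -> first expert decision -> CMA with positive/negative results;
# shared prefix of the CMA-first scenarios (ids follow the workflow figure)
.cma_prefix <- function(p) {
  list(nodes = list(
         dx_node("1", "action", label = "clinical intake"),
         dx_node("2", "decision", label = "Decision 1",
                 cost = p$expert_fee, tat = p$tat_expert),
         dx_node("3", "action", label = "CMA", cost = p$cost_cma,
                 tat = p$tat_cma),
         dx_node("5", "result", label = "CMA positive",
                 result_value = "positive", test_ref = "cma"),
         dx_node("6", "result", label = "CMA negative",
                 result_value = "negative", test_ref = "cma"),
         dx_node("x5", "exit", label = "exit: CMA diagnosis")),
       edges = data.frame(
         from = c("1", "2", "3", "3", "5"),
         to = c("2", "3", "5", "6", "x5"),
         prob = c(1, 1, p$yield_cma, 1 - p$yield_cma, 1),
         stringsAsFactors = FALSE))
}

.es_action <- function(id, p, yield, pos_id, neg_id, exit_pos, exit_neg,
                       tier_label) {
  list(nodes = list(
         dx_node(id, "action", label = paste0("ES (", tier_label, ")"),
                 cost = p$cost_es, tat = p$tat_es),
         dx_node(pos_id, "result", label = "ES positive",
                 result_value = "positive", test_ref = "es"),
         dx_node(neg_id, "result", label = "ES negative",
                 result_value = "negative", test_ref = "es"),
         dx_node(exit_pos, "exit", label = "exit: ES diagnosis"),
         dx_node(exit_neg, "exit", label = "exit: undiagnosed")),
       edges = data.frame(
         from = c(id, id, pos_id, neg_id),
         to = c(pos_id, neg_id, exit_pos, exit_neg),
         prob = c(yield, 1 - yield, 1, 1),
         stringsAsFactors = FALSE))
}

.merge_parts <- function(...) {
  parts <- list(...)
  list(nodes = do.call(c, lapply(parts, `[[`, "nodes")),
       edges = do.call(rbind, lapply(parts, `[[`, "edges")))
}

#' Build an expert-alone case-study scenario tree
#'
#' The four strategies compared in the case study:
#' \enumerate{
#'   \item CMA, then GP after a negative CMA.
#'   \item CMA, then GP, then third-tier ES.
#'   \item CMA, then second-tier ES.
#'   \item First-tier ES only.
#' }
#' Node ids mirror the workflow figure numbering ("1", "2", ...); exit
#' nodes without a printed number use an "x" prefix.  Every human decision
#' node carries the expert fee and consultation time — including decisions
#' whose only option is to exit, unless `free_exit_decisions` is set.
#'
#' @param scenario Scenario number 1-4 (integer or string).
#' @param params A [case_params()] registry.
#' @param free_exit_decisions If `TRUE`, decision nodes all of whose
#'   children are exit nodes carry no fee and no consultation time
#'   (sensitivity analysis on the terminal-review fee).
#' @return A valid `dx_tree` with the three tests registered.
#' @export
build_scenario <- function(scenario, params = case_params(),
                           free_exit_decisions = FALSE) {
  p <- params
  scenario <- as.character(scenario)
  parts <- switch(
    scenario,
    "1" = .merge_parts(
      .cma_prefix(p),
      list(nodes = list(
             dx_node("10", "decision", label = "Decision 2",
                     cost = p$expert_fee, tat = p$tat_expert),
             dx_node("14", "action", label = "gene panel", cost = p$cost_gp,
                     tat = p$tat_gp),
             dx_node("17", "result", label = "GP positive",
                     result_value = "positive", test_ref = "gp"),
             dx_node("18", "result", label = "GP negative",
                     result_value = "negative", test_ref = "gp"),
             dx_node("22", "decision", label = "Decision 3",
                     cost = p$expert_fee, tat = p$tat_expert),
             dx_node("23", "exit", label = "exit: undiagnosed"),
             dx_node("x17", "exit", label = "exit: GP diagnosis")),
           edges = data.frame(
             from = c("6", "10", "14", "14", "17", "18", "22"),
             to = c("10", "14", "17", "18", "x17", "22", "23"),
             prob = c(1, 1, p$yield_gp, 1 - p$yield_gp, 1, 1, 1),
             stringsAsFactors = FALSE))),
    "2" = .merge_parts(
      .cma_prefix(p),
      list(nodes = list(
             dx_node("10", "decision", label = "Decision 2",
                     cost = p$expert_fee, tat = p$tat_expert),
             dx_node("14", "action", label = "gene panel", cost = p$cost_gp,
                     tat = p$tat_gp),
             dx_node("17", "result", label = "GP positive",
                     result_value = "positive", test_ref = "gp"),
             dx_node("18", "result", label = "GP negative",
                     result_value = "negative", test_ref = "gp"),
             dx_node("22", "decision", label = "Decision 3",
                     cost = p$expert_fee, tat = p$tat_expert),
             dx_node("x17", "exit", label = "exit: GP diagnosis")),
           edges = data.frame(
             from = c("6", "10", "14", "14", "17", "18"),
             to = c("10", "14", "17", "18", "x17", "22"),
             prob = c(1, 1, p$yield_gp, 1 - p$yield_gp, 1, 1),
             stringsAsFactors = FALSE)),
      .es_action("24", p, p$yield_es_tier3, "25", "26", "x25", "x26",
                 "third tier"),
      list(nodes = list(),
           edges = data.frame(from = "22", to = "24", prob = 1,
                              stringsAsFactors = FALSE))),
    "3" = .merge_parts(
      .cma_prefix(p),
      list(nodes = list(
             dx_node("10", "decision", label = "Decision 2",
                     cost = p$expert_fee, tat = p$tat_expert)),
           edges = data.frame(from = "6", to = "10", prob = 1,
                              stringsAsFactors = FALSE)),
      .es_action("13", p, p$yield_es_tier2, "15", "16", "x15", "x16",
                 "second tier"),
      list(nodes = list(),
           edges = data.frame(from = "10", to = "13", prob = 1,
                              stringsAsFactors = FALSE))),
    "4" = .merge_parts(
      list(nodes = list(
             dx_node("1", "action", label = "clinical intake"),
             dx_node("2", "decision", label = "Decision 1",
                     cost = p$expert_fee, tat = p$tat_expert)),
           edges = data.frame(from = "1", to = "2", prob = 1,
                              stringsAsFactors = FALSE)),
      .es_action("4", p, p$yield_es_tier1, "7", "8", "x7", "x8",
                 "first tier"),
      list(nodes = list(),
           edges = data.frame(from = "2", to = "4", prob = 1,
                              stringsAsFactors = FALSE))),
    stop("unknown scenario '", scenario, "' (expected 1, 2, 3 or 4)"))

  tree <- dx_tree(parts$nodes, parts$edges, root = "1",
                  tests = .case_tests(p),
                  meta = list(scenario = paste0("scenario-", scenario),
                              prevalence = p$prevalence))
  if (free_exit_decisions) {
    kids <- split(tree$edges, tree$edges$from)
    for (id in names(tree$nodes)) {
      n <- tree$nodes[[id]]
      ch <- kids[[id]]
      if (n$kind == "decision" && !is.null(ch) &&
          all(vapply(ch$to, function(j) tree$nodes[[j]]$kind == "exit",
                     logical(1)))) {
        tree$nodes[[id]]$cost <- 0
        tree$nodes[[id]]$tat <- 0
      }
    }
  }
  tree
}

#' Build the AI-delegated case-study tree
#'
#' Starts from scenario 2 (CMA, GP, third-tier ES) and delegates the
#' post-CMA decision to an AI gate: after a negative CMA the AI action node
#' (`1'`) predicts whether the gene panel will yield a diagnosis.  If the
#' score clears the threshold (`r >= r*`, AI result `2'`) the gene panel is
#' ordered automatically — the branch is fully AI-operated, so neither the
#' replaced decision nor the third-tier review carries an expert fee, and
#' the panel's positive probability is the AI precision.  Otherwise (AI
#' result `3'`) the pathway falls back to the expert decision and
#' second-tier ES of scenario 3.  Automated-branch node ids carry a prime
#' suffix.
#'
#' @param params A [case_params()] registry.
#' @param ai An [ai_config()]; defaults to the registry's reference
#'   precision with an active gate.
#' @return A valid `dx_tree`.
#' @export
build_ai_tree <- function(params = case_params(),
                          ai = ai_config(precision = params$ai_precision)) {
  p <- params
  base <- build_scenario(2, p)
  fb <- .merge_parts(
    list(nodes = list(dx_node("10", "decision", label = "Decision 2",
                              cost = p$expert_fee, tat = p$tat_expert)),
         edges = data.frame(from = "10", to = "13", prob = 1,
                            stringsAsFactors = FALSE)),
    .es_action("13", p, p$yield_es_tier2, "15", "16", "x15", "x16",
               "second tier"))
  fallback <- dx_tree(fb$nodes, fb$edges, root = "10",
                      tests = .case_tests(p))
  out <- delegate(base, decision_id = "10", ai = ai,
                  automated_action_id = "14", fallback_subtree = fallback,
                  automate_branch = TRUE,
                  ai_action_id = "1'", gate_ge_id = "2'", gate_lt_id = "3'")
  automated <- c("14", "17", "18", "22", "24", "25", "26",
                 "x17", "x25", "x26")
  map <- setNames(paste0(automated, "'"), automated)
  out <- .rename_nodes(out, map)
  out$meta$scenario <- "ai-delegation"
  .assert_valid(out)
  out
}

.SWEEP_BOUNDS <- list(
  alpha = c(0, 1), lambda = c(0, Inf), precision = c(0, 1),
  gate_prob = c(0, 1))

#' Sweep a parameter across the case-study strategies
#'
#' Recomputes expected cost, expected effectiveness and effective cost for
#' each requested strategy at every grid point of the swept parameter.
#' Sweepable parameters: `alpha`, `lambda` (utility parameters),
#' `precision`, `gate_prob` (AI configuration; only the `"ai"` strategy
#' responds), or any cost/turnaround/yield/performance field of
#' [case_params()].
#'
#' @param param Name of the parameter to sweep.
#' @param grid Strictly increasing numeric grid of parameter values.
#' @param scenarios Character/numeric vector drawn from
#'   `c("1", "2", "3", "4", "ai")`.
#' @param params A [case_params()] registry for the non-swept values.
#' @param utility A `dx_utility`; defaults to [case_utility()] on `params`.
#' @param ai Base [ai_config()] for the `"ai"` strategy.
#' @return A data frame of class `dx_sweep` with columns `scenario`,
#'   `param_value`, `expected_cost`, `expected_effectiveness`,
#'   `effective_cost`.
#' @export
sweep_grid <- function(param, grid, scenarios = c("1", "2", "3", "4"),
                       params = case_params(), utility = NULL,
                       ai = ai_config(precision = params$ai_precision)) {
  if (length(grid) < 1L) stop("grid must be non-empty")
  if (is.unsorted(grid, strictly = TRUE))
    stop("grid must be strictly increasing")
  scenarios <- as.character(scenarios)
  bad <- setdiff(scenarios, c("1", "2", "3", "4", "ai"))
  if (length(bad)) stop("unknown scenario(s): ", paste(bad, collapse = ", "))
  if (is.null(utility)) utility <- case_utility(params)

  bounds <- .SWEEP_BOUNDS[[param]]
  if (is.null(bounds)) {
    if (!param %in% names(params)) stop("unknown sweep parameter '", param, "'")
    probs <- c("yield_cma", "yield_gp", "yield_es_tier1", "yield_es_tier2",
               "yield_es_tier3", "se_cma", "sp_cma", "se_gp", "sp_gp",
               "se_es", "sp_es", "prevalence", "ai_precision")
    bounds <- if (param %in% probs) c(0, 1) else c(0, Inf)
  }
  if (any(grid < bounds[1] | grid > bounds[2]))
    stop("grid value(s) outside the legal range [", bounds[1], ", ",
         bounds[2], "] of '", param, "'")

  rows <- list()
  for (value in grid) {
    pa <- params; ut <- utility; ai_cfg <- ai
    if (param == "alpha") {
      ut <- utility_params(prevalence = utility$prevalence, alpha = value,
                           lambda = utility$lambda, u_tp = utility$u_tp,
                           u_fp = utility$u_fp, u_tn = utility$u_tn,
                           u_fn = utility$u_fn, pv_mode = utility$pv_mode,
                           no_result_egu = utility$no_result_egu)
    } else if (param == "lambda") {
      ut <- utility_params(prevalence = utility$prevalence,
                           alpha = utility$alpha, lambda = value,
                           u_tp = utility$u_tp, u_fp = utility$u_fp,
                           u_tn = utility$u_tn, u_fn = utility$u_fn,
                           pv_mode = utility$pv_mode,
                           no_result_egu = utility$no_result_egu)
    } else if (param == "precision") {
      ai_cfg$precision <- value
    } else if (param == "gate_prob") {
      ai_cfg$gate_prob <- value
    } else {
      args <- unclass(params); args[[param]] <- value
      pa <- do.call(case_params, args)
      if (param == "prevalence")
        ut <- case_utility(pa, alpha = utility$alpha, lambda = utility$lambda)
    }
    for (s in scenarios) {
      tree <- if (s == "ai") build_ai_tree(pa, ai_cfg)
              else build_scenario(s, pa)
      rep <- cost_effectiveness(tree, ut)
      rows[[length(rows) + 1L]] <-
        data.frame(scenario = s, param_value = value,
                   expected_cost = rep$expected_cost,
                   expected_effectiveness = rep$expected_effectiveness,
                   effective_cost = rep$effective_cost,
                   stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "param") <- param
  class(out) <- c("dx_sweep", "data.frame")
  out
}

#' Case-study AI precision crossover
#'
#' Convenience wrapper around [crossover_precision()] for the bundled case
#' study: the AI-delegated tree is rebuilt at each candidate precision and
#' compared against the chosen expert-alone baselines.
#'
#' @param alpha,lambda Utility parameters of the comparison.
#' @param baselines Scenario labels of the baselines to beat (default
#'   `c("2", "3")`).
#' @param params A [case_params()] registry.
#' @param gate_prob AI gate probability (default 1: automated branch
#'   active).
#' @param tol Bisection tolerance.
#' @return See [crossover_precision()].
#' @export
case_crossover <- function(alpha = 0.5, lambda = 0.03,
                           baselines = c("2", "3"), params = case_params(),
                           gate_prob = 1, tol = 1e-4) {
  ut <- case_utility(params, alpha = alpha, lambda = lambda)
  builder <- function(pr)
    build_ai_tree(params, ai_config(precision = pr, gate_prob = gate_prob))
  base_trees <- lapply(baselines, build_scenario, params = params)
  crossover_precision(builder, base_trees, ut, tol = tol)
}
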