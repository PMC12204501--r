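#' AI delegation configuration
#'
#' Parameters of an AI-delegated decision point: the confidence threshold
#' `r*` above which the AI's recommended test is ordered without expert
#' review, the AI's precision (probability that the automated test returns
#' a positive result given the AI predicted one), the gate probability
#' `q = P(r >= r*)`, and the cost and turnaround time of the AI step
#' itself (both 0 by default: automated inference is assumed free and
#' instantaneous unless configured otherwise).
#'
#' In `"population"` mode the gate probability may lie anywhere in \[0,1\]
#' (the share of patients whose score clears the threshold); in
#' `"patient"` mode the score of a given patient is a fixed number, so the
#' gate probability must be exactly 0 or 1.
#'
#' @param precision AI precision in \[0,1\].
#' @param threshold Score threshold `r*` in \[0,1\] (default 0.8).
#' @param gate_prob Probability that the score clears the threshold
#'   (default 1: the automated branch is active).
#' @param ai_cost,ai_tat Cost and turnaround time (weeks) of the AI action
#'   node.
#' @param mode `"population"` or `"patient"`.
#' @return An object of class `dx_ai_config`.
#' @export
ai_config <- function(precision, threshold = 0.8, gate_prob = 1,
                      ai_cost = 0, ai_tat = 0,
                      mode = c("population", "patient")) {
  mode <- match.arg(mode)
  .check_prob(precision = precision, threshold = threshold,
              gate_prob = gate_prob)
  if (ai_cost < 0 || ai_tat < 0) stop("ai_cost and ai_tat must be >= 0")
  if (mode == "patient" && !gate_prob %in% c(0, 1))
    stop("patient mode requires gate_prob to be exactly 0 or 1")
  structure(list(precision = precision, threshold = threshold,
                 gate_prob = gate_prob, ai_cost = ai_cost, ai_tat = ai_tat,
                 mode = mode),
            class = "dx_ai_config")
}

#' Transition probabilities induced by an AI configuration
#'
#' @param ai A [ai_config()] object.
#' @return Named list: `gate` (probability of the `r >= r*` branch),
#'   `non_gate`, `automated_positive` (the automated test's positive-result
#'   probability, i.e. the AI precision) and `automated_negative`.
#' @export
ai_transition_probabilities <- function(ai) {
  stopifnot(inherits(ai, "dx_ai_config"))
  list(gate = ai$gate_prob, non_gate = 1 - ai$gate_prob,
       automated_positive = ai$precision,
       automated_negative = 1 - ai$precision)
}

# rename node ids throughout a tree (edges, root, path-free fields)
.rename_nodes <- function(tree, map) {
  ren <- function(x) ifelse(x %in% names(map), unname(map[x]), x)
  for (old in names(map)) {
    tree$nodes[[old]]$id <- unname(map[old])
    if (identical(tree$nodes[[old]]$label, old))
      tree$nodes[[old]]$label <- unname(map[old])
  }
  names(tree$nodes) <- ren(names(tree$nodes))
  tree$edges$from <- ren(tree$edges$from)
  tree$edges$to <- ren(tree$edges$to)
  tree$root <- ren(tree$root)
  tree
}

# ids of all nodes in the subtree rooted at `id`
.subtree_ids <- function(tree, id) {
  kids <- split(tree$edges, tree$edges$from)
  out <- character()
  stack <- id
  while (length(stack)) {
    cur <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    out <- c(out, cur)
    ch <- kids[[cur]]
    if (!is.null(ch)) stack <- c(stack, ch$to)
  }
  out
}

#' Rewrite an expert decision point into an AI-delegated gate
#'
#' Replaces a human decision node with the AI-delegation structure: an AI
#' action node (cost `ai$ai_cost`, turnaround `ai$ai_tat`) followed by two
#' AI result nodes partitioned by the confidence threshold.  The
#' `r >= r*` result (probability `ai$gate_prob`) leads directly to the
#' chosen automated action — the replaced decision's fee is no longer
#' incurred because test ordering is automated — and the positive-result
#' probability (diagnostic yield) of that action is set to the AI's
#' precision.  The `r < r*` result (probability `1 - gate_prob`) leads to
#' the supplied fallback subtree, headed by a human decision node and
#' unaffected by AI performance.  Candidate actions of the original
#' decision other than the automated one are dropped.
#'
#' With `automate_branch = TRUE` (default) the automated branch is fully
#' AI-operated: any decision node inside the automated action's subtree
#' also has its fee and consultation time removed and its actor set to
#' `"ai"`.  Set it to `FALSE` to keep downstream expert reviews (and their
#' fees) on the automated branch.
#'
#' When `gate_prob` is exactly 0 or 1 the dead branch is left in place with
#' zero probability mass; the tree remains valid.
#'
#' @param tree A valid `dx_tree`.
#' @param decision_id Id of the decision node to delegate.
#' @param ai An [ai_config()].
#' @param automated_action_id Id of the candidate action (a child of
#'   `decision_id`) the AI orders automatically.
#' @param fallback_subtree A `dx_tree` to attach under the `r < r*` gate;
#'   its node ids must not collide with the ids kept from `tree`.
#' @param automate_branch Zero out decision fees within the automated
#'   branch (see Details).
#' @param ai_action_id,gate_ge_id,gate_lt_id Ids for the inserted nodes;
#'   defaults derive from `decision_id`.
#' @return A valid `dx_tree`.
#' @export
delegate <- function(tree, decision_id, ai, automated_action_id,
                     fallback_subtree, automate_branch = TRUE,
                     ai_action_id = paste0(decision_id, "_ai"),
                     gate_ge_id = paste0(decision_id, "_ge"),
                     gate_lt_id = paste0(decision_id, "_lt")) {
  .assert_valid(tree)
  stopifnot(inherits(ai, "dx_ai_config"), inherits(fallback_subtree, "dx_tree"))
  .assert_valid(fallback_subtree)
  dn <- tree$nodes[[decision_id]]
  if (is.null(dn) || dn$kind != "decision")
    stop("'", decision_id, "' is not a decision node")
  cand <- tree$edges$to[tree$edges$from == decision_id]
  if (!automated_action_id %in% cand)
    stop("'", automated_action_id, "' is not a candidate action of decision '",
         decision_id, "'")

  keep_auto <- .subtree_ids(tree, automated_action_id)
  drop_ids <- setdiff(.subtree_ids(tree, decision_id), keep_auto)
  collisions <- intersect(names(fallback_subtree$nodes),
                          c(setdiff(names(tree$nodes), drop_ids),
                            ai_action_id, gate_ge_id, gate_lt_id))
  if (length(collisions))
    stop("fallback subtree node id(s) collide: ",
         paste(collisions, collapse = ", "))

  nodes <- tree$nodes[setdiff(names(tree$nodes), drop_ids)]
  edges <- tree$edges[!(tree$edges$from %in% drop_ids) &
                        !(tree$edges$to %in% drop_ids), , drop = FALSE]
  # re-target the decision's parent edge (if any) to the AI action node
  parent_edge <- which(tree$edges$to == decision_id)
  if (length(parent_edge)) {
    pe <- tree$edges[parent_edge, , drop = FALSE]
    pe$to <- ai_action_id
    edges <- rbind(edges, pe)
  }
  root <- if (identical(tree$root, decision_id)) ai_action_id else tree$root

  nodes[[ai_action_id]] <- dx_node(ai_action_id, "action", actor = "ai",
                                   label = "AI test recommendation",
                                   cost = ai$ai_cost, tat = ai$ai_tat)
  nodes[[gate_ge_id]] <- dx_node(gate_ge_id, "result", actor = "ai",
                                 label = sprintf("r >= %.4g", ai$threshold),
                                 result_value = "r_ge_threshold")
  nodes[[gate_lt_id]] <- dx_node(gate_lt_id, "result", actor = "ai",
                                 label = sprintf("r < %.4g", ai$threshold),
                                 result_value = "r_lt_threshold")
  nodes <- c(nodes, fallback_subtree$nodes)

  edges <- rbind(edges,
                 data.frame(from = c(ai_action_id, ai_action_id,
                                     gate_ge_id, gate_lt_id),
                            to = c(gate_ge_id, gate_lt_id,
                                   automated_action_id, fallback_subtree$root),
                            prob = c(ai$gate_prob, 1 - ai$gate_prob, 1, 1),
                            stringsAsFactors = FALSE),
                 fallback_subtree$edges)

  # the automated action's yield now reflects AI precision
  res_kids <- edges$to[edges$from == automated_action_id]
  pos <- res_kids[vapply(res_kids, function(id)
    identical(nodes[[id]]$result_value, "positive"), logical(1))]
  neg <- res_kids[vapply(res_kids, function(id)
    identical(nodes[[id]]$result_value, "negative"), logical(1))]
  if (length(pos) != 1L || length(neg) != 1L)
    stop("automated action '", automated_action_id,
         "' must have one positive and one negative result child")
  edges$prob[edges$from == automated_action_id & edges$to == pos] <- ai$precision
  edges$prob[edges$from == automated_action_id & edges$to == neg] <- 1 - ai$precision

  if (automate_branch) {
    for (id in keep_auto) {
      if (nodes[[id]]$kind == "decision") {
        nodes[[id]]$cost <- 0
        nodes[[id]]$tat <- 0
        nodes[[id]]$actor <- "ai"
      }
    }
  }

  tests <- utils::modifyList(tree$tests, fallback_subtree$tests)
  dx_tree(unname(nodes), edges, root = root, tests = tests,
          meta = utils::modifyList(tree$meta, list(ai_delegated = TRUE)))
}

#' Smallest AI precision at which delegation becomes cost-effective
#'
#' Scans the effective cost of the AI-delegated tree over a precision grid,
#' verifies that it is monotone non-increasing (the premise under which
#' bisection is valid; a violation raises an error recommending a dense
#' grid scan), then bisects for the smallest precision whose effective cost
#' does not exceed the best (lowest) effective cost among the baseline
#' trees.
#'
#' @param ai_tree_builder Function mapping a precision in \[0,1\] to a valid
#'   `dx_tree`.
#' @param baselines List of baseline `dx_tree` objects to beat.
#' @param params A [utility_params()] object used for every effective-cost
#'   evaluation.
#' @param tol Bisection tolerance on the precision (default 1e-4).
#' @param grid_n Number of points in the monotonicity pre-scan (default 101).
#' @return The crossover precision (single number, located to within
#'   `tol`, ties broken toward the smaller precision), with attribute
#'   `status = "found"`; or `NA` with `status = "never"` when even
#'   precision 1 does not reach the baselines.
#' @export
crossover_precision <- function(ai_tree_builder, baselines, params,
                                tol = 1e-4, grid_n = 101) {
  stopifnot(is.function(ai_tree_builder), length(baselines) >= 1)
  target <- min(vapply(baselines, effective_cost, numeric(1),
                       params = params))
  f <- function(p) effective_cost(ai_tree_builder(p), params)
  grid <- seq(0, 1, length.out = grid_n)
  vals <- vapply(grid, f, numeric(1))
  slack <- 1e-9 * (1 + max(abs(vals)))
  if (any(diff(vals) > slack))
    stop("effective cost is not monotone non-increasing in precision on the ",
         "pre-scan grid; bisection is invalid -- fall back to a dense grid scan")
  if (vals[1] <= target) {
    out <- 0
    attr(out, "status") <- "found"
    return(out)
  }
  if (vals[grid_n] > target) {
    out <- NA_real_
    attr(out, "status") <- "never"
    return(out)
  }
  lo <- 0; hi <- 1  # invariant: f(lo) > target, f(hi) <= target
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (f(mid) <= target) hi <- mid else lo <- mid
  }
  out <- hi
  attr(out, "status") <- "found"
  out
}
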