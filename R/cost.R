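#' Expected cost of a diagnostic tree by leaf-to-root recursion
#'
#' Computes the cumulative expected cost at every node: a leaf contributes
#' its own cost, and an internal node contributes its cost plus the
#' probability-weighted expected costs of its children,
#' \deqn{EC^+_i = C_i + \sum_j P_{ij}\, EC^+_j.}
#' The recursion runs leaf-to-root over an explicit post-order traversal, so
#' arbitrarily deep trees do not hit interpreter recursion limits.  The same
#' recursion with turnaround time substituted for cost gives the expected
#' turnaround time (valid because expectation is linear along pathways).
#'
#' @param tree A valid `dx_tree`.
#' @return An object of class `dx_cost_report`: a list with
#'   `expected_cost`, `expected_tat`, and `per_node_expected` (named vector
#'   of cumulative expected cost per node; the root entry equals
#'   `expected_cost`).
#' @examples
#' tr <- build_scenario(1)
#' expected_cost(tr)
#' @export
expected_cost <- function(tree) {
  .assert_valid(tree)
  per_cost <- .backprop(tree, "cost")
  per_tat <- .backprop(tree, "tat")
  structure(list(expected_cost = unname(per_cost[tree$root]),
                 expected_tat = unname(per_tat[tree$root]),
                 per_node_expected = per_cost),
            class = "dx_cost_report")
}

# post-order accumulation of one per-node attribute
.backprop <- function(tree, attribute) {
  ids <- names(tree$nodes)
  base <- vapply(tree$nodes, `[[`, numeric(1), attribute)
  kids <- split(tree$edges, tree$edges$from)
  # iterative post-order from the root
  order_out <- character(length(ids)); k <- 0L
  stack <- tree$root
  while (length(stack) > 0L) {
    id <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    k <- k + 1L
    order_out[k] <- id
    ch <- kids[[id]]
    if (!is.null(ch)) stack <- c(stack, ch$to)
  }
  acc <- base
  for (id in rev(order_out[seq_len(k)])) {
    ch <- kids[[id]]
    if (!is.null(ch)) acc[id] <- base[id] + sum(ch$prob * acc[ch$to])
  }
  acc
}

#' Expected value of a per-node attribute
#'
#' Generalisation of [expected_cost()] to a chosen attribute: the same
#' leaf-to-root recursion with either the node cost or the node turnaround
#' time.
#'
#' @param tree A valid `dx_tree`.
#' @param attribute `"cost"` or `"tat"`.
#' @return The expected value at the root (a single number).
#' @export
expected_attribute <- function(tree, attribute = c("cost", "tat")) {
  attribute <- match.arg(attribute)
  .assert_valid(tree)
  unname(.backprop(tree, attribute)[tree$root])
}

#' Monte-Carlo cohort simulation over a diagnostic tree
#'
#' Samples `n` independent root-to-leaf walks, each step drawn from the
#' node's outgoing transition probabilities, and summarises realised cost,
#' turnaround time and final outcomes with Monte-Carlo standard errors.
#' This is an independent stochastic check on the recursive expected-cost
#' computation: the mean simulated cost converges to the value of
#' [expected_cost()].
#'
#' @param tree A valid `dx_tree`.
#' @param n Cohort size (>= 1).
#' @param seed Integer seed; identical seeds reproduce the summary exactly.
#' @return An object of class `dx_cohort`: list with `n`, `mean_cost`,
#'   `se_cost`, `mean_tat`, `se_tat`, `leaf_freq` (named relative
#'   frequencies of terminal leaves) and `outcome_freq` (relative
#'   frequencies of the final result value).
#' @export
simulate_cohort <- function(tree, n, seed) {
  .assert_valid(tree)
  if (length(n) != 1L || is.na(n) || n < 1) stop("n must be >= 1")
  n <- as.integer(n)
  set.seed(as.integer(seed))
  kids <- split(tree$edges, tree$edges$from)
  cost_of <- vapply(tree$nodes, `[[`, numeric(1), "cost")
  tat_of <- vapply(tree$nodes, `[[`, numeric(1), "tat")

  at <- rep.int(tree$root, n)
  cost <- rep.int(cost_of[tree$root], n)
  tat <- rep.int(tat_of[tree$root], n)
  active <- rep.int(TRUE, n)
  while (any(active)) {
    for (id in unique(at[active])) {
      ch <- kids[[id]]
      here <- which(active & at == id)
      if (is.null(ch)) {
        active[here] <- FALSE
        next
      }
      pick <- if (nrow(ch) == 1L) rep.int(1L, length(here))
              else sample.int(nrow(ch), length(here), replace = TRUE,
                              prob = ch$prob)
      nxt <- ch$to[pick]
      at[here] <- nxt
      cost[here] <- cost[here] + cost_of[nxt]
      tat[here] <- tat[here] + tat_of[nxt]
    }
  }

  paths <- enumerate_paths(tree)
  res_by_leaf <- setNames(paths$final_result, paths$leaf)
  outcome <- res_by_leaf[at]
  outcome[is.na(outcome)] <- "none"
  structure(list(n = n, seed = as.integer(seed),
                 mean_cost = mean(cost), se_cost = stats::sd(cost) / sqrt(n),
                 mean_tat = mean(tat), se_tat = stats::sd(tat) / sqrt(n),
                 leaf_freq = table(at) / n,
                 outcome_freq = table(outcome) / n),
            class = "dx_cohort")
}

#' @export
print.dx_cost_report <- function(x, ...) {
  cat(sprintf("<dx_cost_report> expected cost %.2f, expected TAT %.2f weeks\n",
              x$expected_cost, x$expected_tat))
  invisible(x)
}

#' @export
print.dx_cohort <- function(x, ...) {
  cat(sprintf("<dx_cohort> n = %d: mean cost %.2f (SE %.3f), mean TAT %.2f (SE %.4f)\n",
              x$n, x$mean_cost, x$se_cost, x$mean_tat, x$se_tat))
  invisible(x)
}

#' Generate a random valid diagnostic tree
#'
#' Draws a random decision-action-result tree for property testing: node
#' kinds alternate decision -> action -> result, actions branch into a
#' positive/negative result pair, decisions fan out over up to
#' `max_children` actions with Dirichlet-distributed probabilities (unit
#' gamma draws, normalised), and every branch terminates in an exit node by
#' `max_depth` decision tiers.  Costs and turnaround times are uniform
#' draws.  Fully determined by `seed`.
#'
#' @param seed Integer seed.
#' @param max_depth Maximum number of decision tiers (>= 1).
#' @param max_children Maximum actions under a decision (>= 1).
#' @return A valid `dx_tree`.
#' @export
random_tree <- function(seed, max_depth = 4, max_children = 3) {
  set.seed(as.integer(seed))
  nodes <- list()
  edges <- list()
  counter <- new.env(parent = emptyenv()); counter$i <- 0L
  new_id <- function() { counter$i <- counter$i + 1L; sprintf("n%03d", counter$i) }
  add_node <- function(...) {
    n <- dx_node(...)
    nodes[[length(nodes) + 1L]] <<- n
    n$id
  }
  add_edge <- function(from, to, prob)
    edges[[length(edges) + 1L]] <<- data.frame(from = from, to = to,
                                               prob = prob,
                                               stringsAsFactors = FALSE)
  grow_decision <- function(depth) {
    did <- add_node(new_id(), "decision", cost = stats::runif(1, 0, 500),
                    tat = stats::runif(1, 0, 4))
    k <- sample.int(max_children, 1L)
    w <- stats::rgamma(k, 1); w <- w / sum(w)
    for (i in seq_len(k)) {
      aid <- add_node(new_id(), "action", cost = stats::runif(1, 0, 5000),
                      tat = stats::runif(1, 0, 8))
      add_edge(did, aid, w[i])
      q <- stats::runif(1, 0.05, 0.95)
      pos <- add_node(new_id(), "result", result_value = "positive")
      neg <- add_node(new_id(), "result", result_value = "negative")
      add_edge(aid, pos, q)
      add_edge(aid, neg, 1 - q)
      xp <- add_node(new_id(), "exit")
      add_edge(pos, xp, 1)
      if (depth < max_depth && stats::runif(1) < 0.6) {
        add_edge(neg, grow_decision(depth + 1L), 1)
      } else {
        xn <- add_node(new_id(), "exit")
        add_edge(neg, xn, 1)
      }
    }
    did
  }
  root <- grow_decision(1L)
  dx_tree(nodes, do.call(rbind, edges), root = root)
}
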