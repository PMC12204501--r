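#' Create a diagnostic-tree node
#'
#' Nodes are the building blocks of a diagnostic tree.  Four kinds are
#' distinguished: `decision` (a clinical judgement point, typically carrying
#' an expert fee and consultation time), `action` (execution of a diagnostic
#' step such as a test), `result` (the dichotomous outcome of an action) and
#' `exit` (termination of the process).
#'
#' @param id Unique node identifier (string).
#' @param kind One of `"decision"`, `"action"`, `"result"`, `"exit"`.
#' @param actor `"human"` (default) or `"ai"`; AI nodes model automated steps.
#' @param label Free-text description; defaults to the id.
#' @param cost Direct monetary cost incurred at the node (>= 0).
#' @param tat Turnaround time in weeks accrued at the node (>= 0).
#' @param result_value For result nodes only: `"positive"`, `"negative"`, or
#'   a gate label such as `"r_ge_threshold"` for AI confidence gates.
#' @param test_ref Optional key into the tree's test-performance registry,
#'   linking a result node to the sensitivity/specificity of the test that
#'   produced it.
#' @param terminal Logical; marks a result node that is allowed to be a leaf.
#'
#' @return A plain list with class-free node fields, consumed by [dx_tree()].
#' @seealso [dx_tree()], [parse_tree()]
#' @export
dx_node <- function(id, kind, actor = "human", label = id, cost = 0, tat = 0,
                    result_value = NULL, test_ref = NULL, terminal = FALSE) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  kind <- match.arg(kind, c("decision", "action", "result", "exit"))
  actor <- match.arg(actor, c("human", "ai"))
  list(id = id, kind = kind, actor = actor, label = label,
       cost = as.numeric(cost), tat = as.numeric(tat),
       result_value = result_value, test_ref = test_ref,
       terminal = isTRUE(terminal))
}

#' Assemble a diagnostic tree
#'
#' A diagnostic tree is a rooted tree whose nodes describe decisions, actions
#' and test results, and whose edges carry transition probabilities.  The
#' outgoing probabilities of every internal node must sum to one; the
#' transition from a result node onwards is always trivial (a single child).
#'
#' @param nodes List of nodes built with [dx_node()].
#' @param edges Data frame with columns `from`, `to`, `prob`.
#' @param root Id of the root node; inferred (the unique node without a
#'   parent) when omitted.
#' @param tests Named list of test-performance entries
#'   `list(se = ..., sp = ...)`, keyed by test name.
#' @param meta Free-form annotation list (scenario name, default prevalence).
#' @param validate If `TRUE` (default) the tree is checked with
#'   [validate_tree()] and construction fails on any violation.
#'
#' @return An object of class `dx_tree`.
#' @export
dx_tree <- function(nodes, edges, root = NULL, tests = list(), meta = list(),
                    validate = TRUE) {
  ids <- vapply(nodes, `[[`, character(1), "id")
  if (anyDuplicated(ids))
    stop("duplicate node id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  names(nodes) <- ids
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (nrow(edges) == 0L)
    edges <- data.frame(from = character(), to = character(),
                        prob = numeric(), stringsAsFactors = FALSE)
  stopifnot(all(c("from", "to", "prob") %in% names(edges)))
  edges <- edges[, c("from", "to", "prob")]
  edges$from <- as.character(edges$from)
  edges$to <- as.character(edges$to)
  edges$prob <- as.numeric(edges$prob)
  if (is.null(root)) {
    candidates <- setdiff(ids, edges$to)
    if (length(candidates) != 1L)
      stop("cannot infer root: ", length(candidates), " parentless nodes")
    root <- candidates
  }
  tree <- structure(list(nodes = nodes, edges = edges, root = root,
                         tests = tests, meta = meta),
                    class = "dx_tree")
  if (validate) {
    v <- validate_tree(tree)
    if (nrow(v) > 0L)
      stop("invalid diagnostic tree:\n  ",
           paste(sprintf("[%s] %s", v$node, v$message), collapse = "\n  "))
  }
  tree
}

# outgoing edges indexed by parent id
.children_map <- function(tree) {
  split(tree$edges, factor(tree$edges$from, levels = names(tree$nodes)))
}

.PROB_TOL <- 1e-9  # absolute tolerance on outgoing probability sums

#' Validate a diagnostic tree
#'
#' Checks every structural invariant of the tree representation: unique
#' root, single parent per node, acyclicity, reachability, probability
#' bounds and per-node normalisation (outgoing probabilities sum to one
#' within 1e-9), result-value rules, trivial result transitions, legal
#' leaves and non-negative costs and turnaround times.  Violations are data,
#' not errors, so invalid documents can be inspected.
#'
#' @param tree A `dx_tree` (possibly built with `validate = FALSE`).
#' @return A data frame with columns `node` and `message`, ordered by node
#'   id; zero rows means the tree is valid.
#' @export
validate_tree <- function(tree) {
  stopifnot(inherits(tree, "dx_tree"))
  bad <- list()
  flag <- function(node, message)
    bad[[length(bad) + 1L]] <<- data.frame(node = node, message = message,
                                           stringsAsFactors = FALSE)
  ids <- names(tree$nodes)
  e <- tree$edges

  unknown <- setdiff(unique(c(e$from, e$to)), ids)
  for (u in unknown) flag(u, "edge endpoint is not a declared node")
  e <- e[e$from %in% ids & e$to %in% ids, , drop = FALSE]

  if (!tree$root %in% ids) flag(tree$root, "declared root is not a node")

  indeg <- table(factor(e$to, levels = ids))
  for (id in ids) {
    n <- tree$nodes[[id]]
    if (n$cost < 0) flag(id, "negative cost")
    if (n$tat < 0) flag(id, "negative turnaround time")
    if (n$kind == "result" && is.null(n$result_value))
      flag(id, "result node lacks result_value")
    if (n$kind != "result" && !is.null(n$result_value))
      flag(id, "result_value on a non-result node")
    if (!is.null(n$test_ref) && !n$test_ref %in% names(tree$tests))
      flag(id, sprintf("test_ref '%s' missing from test registry", n$test_ref))
    if (id == tree$root) {
      if (indeg[[id]] > 0L) flag(id, "root has a parent")
    } else if (indeg[[id]] != 1L) {
      flag(id, sprintf("node has %d parents (expected 1)", indeg[[id]]))
    }
  }

  for (i in seq_len(nrow(e))) {
    if (is.na(e$prob[i]) || e$prob[i] < 0 || e$prob[i] > 1)
      flag(e$from[i], sprintf("edge to '%s' has probability outside [0,1]",
                              e$to[i]))
  }

  kids <- split(e, e$from)
  for (id in names(kids)) {
    n <- tree$nodes[[id]]
    s <- sum(kids[[id]]$prob)
    if (abs(s - 1) > .PROB_TOL)
      flag(id, sprintf("outgoing probabilities sum to %.12g, not 1", s))
    if (n$kind == "exit")
      flag(id, "exit node has outgoing edges")
    if (n$kind == "result" && nrow(kids[[id]]) > 1L)
      flag(id, "non-trivial result transition (result node with >1 child)")
  }

  leaves <- setdiff(ids, names(kids))
  for (id in leaves) {
    n <- tree$nodes[[id]]
    if (!(n$kind == "exit" || (n$kind == "result" && isTRUE(n$terminal))))
      flag(id, "leaf is neither an exit node nor a terminal result node")
  }

  # cycle / reachability scan from the root (iterative DFS)
  if (tree$root %in% ids) {
    state <- setNames(rep.int(0L, length(ids)), ids)  # 0 new, 1 open, 2 done
    stack <- list(list(id = tree$root, next_child = 1L))
    state[tree$root] <- 1L
    cyclic <- character()
    while (length(stack) > 0L) {
      top <- stack[[length(stack)]]
      ch <- kids[[top$id]]
      if (!is.null(ch) && top$next_child <= nrow(ch)) {
        stack[[length(stack)]]$next_child <- top$next_child + 1L
        nxt <- ch$to[top$next_child]
        if (state[nxt] == 1L) {
          cyclic <- c(cyclic, nxt)
        } else if (state[nxt] == 0L) {
          state[nxt] <- 1L
          stack[[length(stack) + 1L]] <- list(id = nxt, next_child = 1L)
        }
      } else {
        state[top$id] <- 2L
        stack[[length(stack)]] <- NULL
      }
    }
    for (id in unique(cyclic)) flag(id, "cycle detected through this node")
    for (id in ids[state == 0L]) flag(id, "node unreachable from the root")
  }

  out <- if (length(bad)) do.call(rbind, bad)
         else data.frame(node = character(), message = character(),
                         stringsAsFactors = FALSE)
  out <- out[order(out$node, out$message), , drop = FALSE]
  rownames(out) <- NULL
  out
}

.assert_valid <- function(tree) {
  v <- validate_tree(tree)
  if (nrow(v) > 0L)
    stop("invalid diagnostic tree:\n  ",
         paste(sprintf("[%s] %s", v$node, v$message), collapse = "\n  "))
  invisible(tree)
}

#' Enumerate all root-to-leaf pathways
#'
#' Walks the tree depth-first and returns one record per pathway: its
#' probability (product of edge probabilities), accumulated cost and
#' turnaround time (sums of node attributes along the pathway), and the
#' value and test of the last dichotomous result node before the leaf.
#' Pathway probabilities sum to one on a valid tree.
#'
#' @param tree A valid `dx_tree`.
#' @return A data frame of class `dx_paths` with columns `leaf`, `prob`,
#'   `cost`, `tat`, `final_result`, `final_test` and a list column `nodes`
#'   holding the full node-id sequence.
#' @export
enumerate_paths <- function(tree) {
  .assert_valid(tree)
  kids <- split(tree$edges, tree$edges$from)
  recs <- list()
  walk <- function(id, prob, cost, tat, seq_ids) {
    n <- tree$nodes[[id]]
    cost <- cost + n$cost
    tat <- tat + n$tat
    seq_ids <- c(seq_ids, id)
    ch <- kids[[id]]
    if (is.null(ch)) {
      final_result <- NA_character_
      final_test <- NA_character_
      for (j in rev(seq_ids)) {
        nj <- tree$nodes[[j]]
        if (nj$kind == "result" &&
            !is.null(nj$result_value) &&
            nj$result_value %in% c("positive", "negative")) {
          final_result <- nj$result_value
          final_test <- if (is.null(nj$test_ref)) NA_character_ else nj$test_ref
          break
        }
      }
      recs[[length(recs) + 1L]] <<- list(leaf = id, prob = prob, cost = cost,
                                         tat = tat,
                                         final_result = final_result,
                                         final_test = final_test,
                                         nodes = seq_ids)
    } else {
      for (i in seq_len(nrow(ch)))
        walk(ch$to[i], prob * ch$prob[i], cost, tat, seq_ids)
    }
  }
  walk(tree$root, 1, 0, 0, character())
  out <- data.frame(
    leaf = vapply(recs, `[[`, character(1), "leaf"),
    prob = vapply(recs, `[[`, numeric(1), "prob"),
    cost = vapply(recs, `[[`, numeric(1), "cost"),
    tat = vapply(recs, `[[`, numeric(1), "tat"),
    final_result = vapply(recs, `[[`, character(1), "final_result"),
    final_test = vapply(recs, `[[`, character(1), "final_test"),
    stringsAsFactors = FALSE)
  out$nodes <- lapply(recs, `[[`, "nodes")
  class(out) <- c("dx_paths", "data.frame")
  out
}

# ---- serialization ----------------------------------------------------------

.node_to_json_list <- function(n) {
  out <- list(actor = n$actor, cost = n$cost, id = n$id, kind = n$kind,
              label = n$label)
  if (!is.null(n$result_value)) out$result_value <- n$result_value
  out$tat <- n$tat
  if (isTRUE(n$terminal)) out$terminal <- TRUE
  if (!is.null(n$test_ref)) out$test_ref <- n$test_ref
  out
}

#' Serialize a diagnostic tree to its JSON document form
#'
#' The document has top-level keys `edges`, `meta`, `nodes`, `root`, `tests`;
#' keys are emitted in sorted order and nodes/edges in id order, so output is
#' byte-stable and [parse_tree()] round-trips it field for field.
#'
#' @param tree A valid `dx_tree`.
#' @return A single JSON string (UTF-8, two-space indent).
#' @seealso [write_tree()], [parse_tree()]
#' @export
serialize_tree <- function(tree) {
  .assert_valid(tree)
  ids <- sort(names(tree$nodes))
  e <- tree$edges[order(tree$edges$from, tree$edges$to), , drop = FALSE]
  edges <- lapply(seq_len(nrow(e)), function(i)
    list(from = e$from[i], prob = e$prob[i], to = e$to[i]))
  tests <- if (length(tree$tests)) tree$tests[order(names(tree$tests))]
           else list()
  tests <- lapply(tests, function(t) list(se = t$se, sp = t$sp))
  meta <- if (length(tree$meta)) tree$meta[order(names(tree$meta))] else list()
  doc <- list(edges = edges,
              meta = if (length(meta)) meta else structure(list(), names = character()),
              nodes = lapply(tree$nodes[ids], .node_to_json_list),
              root = tree$root,
              tests = if (length(tests)) tests else structure(list(), names = character()))
  as.character(jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA,
                                pretty = 2))
}

#' @rdname serialize_tree
#' @param path File path to write to.
#' @export
write_tree <- function(tree, path) {
  writeLines(serialize_tree(tree), path, useBytes = TRUE)
  invisible(path)
}

#' Parse a diagnostic-tree JSON document
#'
#' Applies defaults (`actor` human, `cost` 0, `tat` 0), then validates the
#' result; any schema or invariant violation raises an error naming the
#' offending node or edge.
#'
#' @param text JSON document as a single string or character vector of lines.
#' @return A validated `dx_tree`.
#' @export
parse_tree <- function(text) {
  doc <- jsonlite::fromJSON(paste(text, collapse = "\n"),
                            simplifyVector = FALSE)
  for (key in c("nodes", "edges", "root"))
    if (is.null(doc[[key]])) stop("tree document lacks top-level key '", key, "'")
  nodes <- lapply(doc$nodes, function(n) {
    if (is.null(n$id)) stop("node without an 'id' field")
    if (is.null(n$kind)) stop("node '", n$id, "' lacks a 'kind' field")
    dx_node(id = as.character(n$id), kind = n$kind,
            actor = if (is.null(n$actor)) "human" else n$actor,
            label = if (is.null(n$label)) as.character(n$id) else n$label,
            cost = if (is.null(n$cost)) 0 else n$cost,
            tat = if (is.null(n$tat)) 0 else n$tat,
            result_value = n$result_value, test_ref = n$test_ref,
            terminal = isTRUE(n$terminal))
  })
  edges <- if (length(doc$edges) == 0L) {
    data.frame(from = character(), to = character(), prob = numeric())
  } else {
    do.call(rbind, lapply(doc$edges, function(ed) {
      for (key in c("from", "to", "prob"))
        if (is.null(ed[[key]]))
          stop("edge lacks required field '", key, "'")
      data.frame(from = as.character(ed$from), to = as.character(ed$to),
                 prob = as.numeric(ed$prob), stringsAsFactors = FALSE)
    }))
  }
  tests <- lapply(doc$tests, function(t) {
    if (is.null(t$se) || is.null(t$sp))
      stop("test registry entries need 'se' and 'sp'")
    list(se = as.numeric(t$se), sp = as.numeric(t$sp))
  })
  dx_tree(nodes, edges, root = as.character(doc$root), tests = tests,
          meta = if (is.null(doc$meta)) list() else doc$meta)
}

#' @rdname parse_tree
#' @param path File path of a tree document.
#' @export
read_tree <- function(path) parse_tree(readLines(path, warn = FALSE))

#' @export
print.dx_tree <- function(x, ...) {
  kinds <- table(vapply(x$nodes, `[[`, character(1), "kind"))
  cat(sprintf("<dx_tree> %d nodes (%s), root '%s'\n",
              length(x$nodes),
              paste(sprintf("%d %s", kinds, names(kinds)), collapse = ", "),
              x$root))
  if (!is.null(x$meta$scenario))
    cat("  scenario:", x$meta$scenario, "\n")
  if (length(x$tests))
    cat("  tests:", paste(names(x$tests), collapse = ", "), "\n")
  invisible(x)
}
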