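#' Positive predictive value of a dichotomous test
#'
#' Bayes' rule applied to a positive result:
#' \deqn{PPV = \frac{Se\,p}{Se\,p + (1-Sp)(1-p)}.}
#'
#' @param se Sensitivity in \[0,1\].
#' @param sp Specificity in \[0,1\].
#' @param p Disease prevalence in \[0,1\].
#' @return Probability that a positive result is a true positive.
#' @export
ppv <- function(se, sp, p) {
  .check_prob(se = se, sp = sp, p = p)
  den <- se * p + (1 - sp) * (1 - p)
  if (any(den <= 0))
    stop("PPV undefined: the test never returns a positive result")
  se * p / den
}

#' Negative predictive value of a dichotomous test
#'
#' \deqn{NPV = \frac{Sp\,(1-p)}{Sp\,(1-p) + (1-Se)\,p}.}
#'
#' @inheritParams ppv
#' @return Probability that a negative result is a true negative.
#' @export
npv <- function(se, sp, p) {
  .check_prob(se = se, sp = sp, p = p)
  den <- sp * (1 - p) + (1 - se) * p
  if (any(den <= 0))
    stop("NPV undefined: the test never returns a negative result")
  sp * (1 - p) / den
}

#' Post-test prevalence after a negative result
#'
#' The probability of disease given a negative result,
#' \eqn{(1-Se)p / ((1-Se)p + Sp(1-p))}, identically `1 - npv(se, sp, p)`.
#' Used to chain prevalence through a sequence of negative tier results when
#' predictive values are compounded serially.
#'
#' @inheritParams ppv
#' @return Updated prevalence in \[0,1\].
#' @export
posterior_after_negative <- function(p, se, sp) {
  .check_prob(se = se, sp = sp, p = p)
  den <- (1 - se) * p + sp * (1 - p)
  if (any(den <= 0))
    stop("posterior undefined: the test never returns a negative result")
  (1 - se) * p / den
}

.check_prob <- function(...) {
  args <- list(...)
  for (nm in names(args)) {
    x <- args[[nm]]
    if (any(is.na(x)) || any(x < 0) || any(x > 1))
      stop("'", nm, "' must lie in [0,1]")
  }
  invisible(TRUE)
}

#' Utility parameters for effectiveness scoring
#'
#' Bundles the parameters of the outcome-state utility
#' \eqn{U(S) = \alpha\,EGU + (1-\alpha)\,e^{-\lambda\,TAT}}: the accuracy
#' weight `alpha`, the delay decay rate `lambda` (per week), the utilities
#' of the four diagnostic outcomes, the disease prevalence, and how
#' predictive values are computed along a multi-tier pathway.
#'
#' @param prevalence Pre-test disease probability in \[0,1\].
#' @param alpha Weight on diagnostic accuracy versus timeliness, in \[0,1\].
#' @param lambda Exponential decay rate of utility per week of delay
#'   (>= 0; the bundled case study restricts it to \[0.01, 0.1\]).
#' @param u_tp,u_tn Utilities of true positive / true negative results, in
#'   \[0,1\].
#' @param u_fp,u_fn Utilities (disutilities) of false positive / false
#'   negative results, in \[-1,0\].
#' @param pv_mode `"final_test"` (default): predictive values use the final
#'   test's sensitivity/specificity at the baseline prevalence.
#'   `"serial_bayes"`: the prevalence is updated with
#'   [posterior_after_negative()] after each preceding negative tier result
#'   before the final test's predictive value is formed.
#' @param no_result_egu Expected gain in utility assigned to pathways that
#'   terminate without a dichotomous result (default 0, the neutral
#'   utility); the delay term still applies.
#' @return An object of class `dx_utility`.
#' @export
utility_params <- function(prevalence, alpha = 0.5, lambda = 0.03,
                           u_tp = 1, u_fp = -1, u_tn = 1, u_fn = -1,
                           pv_mode = c("final_test", "serial_bayes"),
                           no_result_egu = 0) {
  pv_mode <- match.arg(pv_mode)
  .check_prob(prevalence = prevalence, alpha = alpha)
  if (lambda < 0) stop("'lambda' must be >= 0")
  if (u_tp < 0 || u_tp > 1 || u_tn < 0 || u_tn > 1)
    stop("'u_tp' and 'u_tn' must lie in [0,1]")
  if (u_fp < -1 || u_fp > 0 || u_fn < -1 || u_fn > 0)
    stop("'u_fp' and 'u_fn' must lie in [-1,0]")
  structure(list(prevalence = prevalence, alpha = alpha, lambda = lambda,
                 u_tp = u_tp, u_fp = u_fp, u_tn = u_tn, u_fn = u_fn,
                 pv_mode = pv_mode, no_result_egu = no_result_egu),
            class = "dx_utility")
}

#' Expected gain in utility of a final diagnostic outcome
#'
#' A positive final result gains \eqn{PPV\,U_{TP} + (1-PPV)\,U_{FP}}; a
#' negative one gains \eqn{NPV\,U_{TN} + (1-NPV)\,U_{FN}}; a pathway with no
#' dichotomous result receives `params$no_result_egu`.
#'
#' @param outcome `"positive"`, `"negative"` or `"none"`.
#' @param ppv,npv Predictive values of the test that produced the final
#'   result (only the one matching `outcome` is used).
#' @param params A [utility_params()] object.
#' @return Expected gain in utility, in \[-1,1\].
#' @export
expected_gain_utility <- function(outcome = c("positive", "negative", "none"),
                                  ppv = NULL, npv = NULL, params) {
  outcome <- match.arg(outcome)
  switch(outcome,
         positive = ppv * params$u_tp + (1 - ppv) * params$u_fp,
         negative = npv * params$u_tn + (1 - npv) * params$u_fn,
         none = params$no_result_egu)
}

#' Utility of one outcome state
#'
#' Combines diagnostic gain and timeliness:
#' \eqn{U = \alpha\,EGU + (1-\alpha)\,e^{-\lambda\,TAT}}.
#'
#' @param egu Expected gain in utility of the final outcome.
#' @param tat Accumulated turnaround time of the pathway, in weeks (>= 0).
#' @param params A [utility_params()] object.
#' @return Utility of the outcome state.
#' @export
outcome_utility <- function(egu, tat, params) {
  if (any(tat < 0)) stop("'tat' must be >= 0")
  params$alpha * egu + (1 - params$alpha) * exp(-params$lambda * tat)
}

# EGU of one enumerated pathway under the chosen predictive-value mode
.path_egu <- function(tree, path_nodes, final_result, final_test, params) {
  if (is.na(final_result)) return(params$no_result_egu)
  if (is.na(final_test))
    stop("terminal result node on pathway [",
         paste(path_nodes, collapse = " > "),
         "] lacks a test_ref; cannot form predictive values")
  p <- params$prevalence
  if (params$pv_mode == "serial_bayes") {
    # update prevalence through every *preceding* negative tier result
    last_final <- max(which(vapply(path_nodes, function(j) {
      nj <- tree$nodes[[j]]
      nj$kind == "result" && !is.null(nj$result_value) &&
        nj$result_value %in% c("positive", "negative")
    }, logical(1))))
    for (j in path_nodes[seq_len(last_final - 1L)]) {
      nj <- tree$nodes[[j]]
      if (nj$kind == "result" && identical(nj$result_value, "negative") &&
          !is.null(nj$test_ref)) {
        perf <- tree$tests[[nj$test_ref]]
        p <- posterior_after_negative(p, perf$se, perf$sp)
      }
    }
  }
  perf <- tree$tests[[final_test]]
  if (is.null(perf))
    stop("test_ref '", final_test, "' missing from the test registry")
  if (final_result == "positive")
    expected_gain_utility("positive", ppv = ppv(perf$se, perf$sp, p),
                          params = params)
  else
    expected_gain_utility("negative", npv = npv(perf$se, perf$sp, p),
                          params = params)
}

#' Expected effectiveness of a diagnostic tree
#'
#' Enumerates all root-to-leaf pathways, scores each terminal outcome state
#' (expected gain in utility from the final test's predictive values,
#' delay penalty from the pathway's accumulated turnaround time) and
#' returns the probability-weighted sum of those utilities.  Pathways whose
#' final result node carries a numeric value are rejected: only dichotomous
#' results have a utility model.
#'
#' @param tree A valid `dx_tree` whose terminal result nodes resolve in the
#'   test registry.
#' @param params A [utility_params()] object.
#' @return An object of class `dx_effectiveness`: list with
#'   `expected_effectiveness` and `per_path` (the [enumerate_paths()] table
#'   extended with `egu` and `utility` columns).
#' @export
expected_effectiveness <- function(tree, params) {
  stopifnot(inherits(params, "dx_utility"))
  paths <- enumerate_paths(tree)
  for (i in seq_len(nrow(paths))) {
    for (j in paths$nodes[[i]]) {
      nj <- tree$nodes[[j]]
      if (nj$kind == "result" && is.numeric(nj$result_value))
        stop("numeric result values are unsupported by the utility model ",
             "(node '", j, "')")
    }
  }
  egu <- vapply(seq_len(nrow(paths)), function(i)
    .path_egu(tree, paths$nodes[[i]], paths$final_result[i],
              paths$final_test[i], params), numeric(1))
  util <- outcome_utility(egu, paths$tat, params)
  paths$egu <- egu
  paths$utility <- util
  structure(list(expected_effectiveness = sum(paths$prob * util),
                 per_path = paths),
            class = "dx_effectiveness")
}

#' Effective cost of a diagnostic tree
#'
#' The ratio of expected diagnostic cost to expected effectiveness — cost
#' per unit of effectiveness, the summary cost-effectiveness metric.  An
#' explicit error is raised when the expected effectiveness is not strictly
#' positive, rather than returning an infinite or negative ratio.
#'
#' @inheritParams expected_effectiveness
#' @return Money per unit effectiveness (single number).
#' @export
effective_cost <- function(tree, params) {
  cost_effectiveness(tree, params)$effective_cost
}

#' Full cost-effectiveness report
#'
#' Runs both the expected-cost recursion and the pathway-level
#' effectiveness scoring and combines them into one report.
#'
#' @inheritParams expected_effectiveness
#' @return An object of class `dx_cea`: list with `expected_cost`,
#'   `expected_tat`, `expected_effectiveness`, `effective_cost` and the
#'   `per_path` table.
#' @examples
#' tr <- build_scenario(1)
#' cost_effectiveness(tr, case_utility())
#' @export
cost_effectiveness <- function(tree, params) {
  cost <- expected_cost(tree)
  eff <- expected_effectiveness(tree, params)
  if (eff$expected_effectiveness <= 0)
    stop("expected effectiveness is not positive (",
         format(eff$expected_effectiveness),
         "); effective cost is undefined")
  structure(list(expected_cost = cost$expected_cost,
                 expected_tat = cost$expected_tat,
                 expected_effectiveness = eff$expected_effectiveness,
                 effective_cost = cost$expected_cost / eff$expected_effectiveness,
                 per_path = eff$per_path),
            class = "dx_cea")
}

#' @export
print.dx_cea <- function(x, digits = 4, ...) {
  cat("<dx_cea>\n")
  cat(sprintf("  expected cost:          %.*f\n", 2, x$expected_cost))
  cat(sprintf("  expected TAT (weeks):   %.*f\n", 2, x$expected_tat))
  cat(sprintf("  expected effectiveness: %.*f\n", digits,
              x$expected_effectiveness))
  cat(sprintf("  effective cost:         %.*f\n", 2, x$effective_cost))
  cat(sprintf("  pathways: %d\n", nrow(x$per_path)))
  invisible(x)
}

#' @export
print.dx_effectiveness <- function(x, digits = 4, ...) {
  cat(sprintf("<dx_effectiveness> %.*f over %d pathways\n", digits,
              x$expected_effectiveness, nrow(x$per_path)))
  invisible(x)
}
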