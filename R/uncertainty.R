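#' Describe the distribution of one uncertain parameter
#'
#' Distribution specifications drive probabilistic sensitivity analysis.
#' Supported families and their parameters:
#' `point` (`value`), `gamma` (`shape`, `rate`), `normal` (`mean`, `sd`),
#' `beta` (`shape1`, `shape2`), `uniform` (`min`, `max`).  An optional
#' truncation interval is enforced by rejection sampling.
#'
#' @param family Distribution family name.
#' @param ... Family parameters (see Details).
#' @param truncation Optional length-2 numeric `c(low, high)`.
#' @return An object of class `dx_dist`.
#' @export
dist_spec <- function(family = c("point", "gamma", "normal", "beta",
                                 "uniform"),
                      ..., truncation = NULL) {
  family <- match.arg(family)
  pars <- list(...)
  need <- switch(family,
                 point = "value",
                 gamma = c("shape", "rate"),
                 normal = c("mean", "sd"),
                 beta = c("shape1", "shape2"),
                 uniform = c("min", "max"))
  missing <- setdiff(need, names(pars))
  if (length(missing))
    stop("family '", family, "' needs parameter(s): ",
         paste(missing, collapse = ", "))
  pars <- pars[need]
  if (family %in% c("gamma", "beta") && any(unlist(pars) <= 0))
    stop("'", family, "' parameters must be positive")
  if (family == "normal" && pars$sd < 0) stop("'sd' must be >= 0")
  if (family == "uniform" && pars$min >= pars$max)
    stop("'min' must be below 'max'")
  if (!is.null(truncation)) {
    stopifnot(length(truncation) == 2L, truncation[1] < truncation[2])
  }
  structure(list(family = family, parameters = pars,
                 truncation = truncation),
            class = "dx_dist")
}

# theoretical mean/variance where closed forms exist
.dist_moments <- function(spec) {
  p <- spec$parameters
  switch(spec$family,
         point = c(mean = p$value, var = 0),
         gamma = c(mean = p$shape / p$rate, var = p$shape / p$rate^2),
         normal = c(mean = p$mean, var = p$sd^2),
         beta = {
           s <- p$shape1 + p$shape2
           c(mean = p$shape1 / s,
             var = p$shape1 * p$shape2 / (s^2 * (s + 1)))
         },
         uniform = c(mean = (p$min + p$max) / 2,
                     var = (p$max - p$min)^2 / 12))
}

.MAX_REJECTION_RESAMPLES <- 1000L

.draw_one_spec <- function(spec, n) {
  p <- spec$parameters
  rdraw <- switch(spec$family,
                  point = function(k) rep.int(p$value, k),
                  gamma = function(k) stats::rgamma(k, shape = p$shape,
                                                   rate = p$rate),
                  normal = function(k) stats::rnorm(k, p$mean, p$sd),
                  beta = function(k) stats::rbeta(k, p$shape1, p$shape2),
                  uniform = function(k) stats::runif(k, p$min, p$max))
  x <- rdraw(n)
  if (!is.null(spec$truncation)) {
    lo <- spec$truncation[1]; hi <- spec$truncation[2]
    bad <- which(x < lo | x > hi)
    for (i in bad) {
      tries <- 0L
      repeat {
        cand <- rdraw(1L)
        tries <- tries + 1L
        if (cand >= lo && cand <= hi) { x[i] <- cand; break }
        if (tries >= .MAX_REJECTION_RESAMPLES)
          stop("truncation [", lo, ", ", hi, "] rejected ",
               .MAX_REJECTION_RESAMPLES, " consecutive draws")
      }
    }
  }
  x
}

#' Sample joint parameter draws
#'
#' Draws `n` independent joint samples from a named registry of
#' [dist_spec()] objects, reproducibly for a fixed seed.  Truncated
#' families are resampled by rejection with a cap of 1000 attempts per
#' value.
#'
#' @param specs Named list of [dist_spec()] objects.
#' @param n Number of draws (>= 1).
#' @param seed Integer seed.
#' @return A data frame with one column per spec and `n` rows.
#' @export
sample_parameters <- function(specs, n, seed) {
  stopifnot(length(specs) >= 1, !is.null(names(specs)),
            all(nzchar(names(specs))))
  if (length(n) != 1L || is.na(n) || n < 1) stop("n must be >= 1")
  n <- as.integer(n)
  set.seed(as.integer(seed))
  cols <- lapply(specs, .draw_one_spec, n = n)
  as.data.frame(cols, optional = TRUE)
}

#' Reference distributions of the case-study parameters
#'
#' The uncertain parameters of the case study with their reference
#' distributions: CMA cost Gamma(shape 2010, rate 2.44), GP cost
#' Uniform(1450, 1750), ES cost Normal(4589.4, 45) truncated at zero, and
#' Beta yields for CMA (154, 1382), GP (24, 89), first-tier ES (27, 46) and
#' third-tier ES (228, 464); the second-tier ES yield is a point value
#' (0.35).  The Gamma is parameterised shape/rate — its mean (~823.8)
#' matches the deterministic CMA cost — and the Normal as mean/sd.
#'
#' @return Named list of [dist_spec()] objects keyed by [case_params()]
#'   field names.
#' @export
case_dist_specs <- function() {
  list(cost_cma = dist_spec("gamma", shape = 2010, rate = 2.44),
       cost_gp = dist_spec("uniform", min = 1450, max = 1750),
       cost_es = dist_spec("normal", mean = 4589.4, sd = 45,
                           truncation = c(0, Inf)),
       yield_cma = dist_spec("beta", shape1 = 154, shape2 = 1382),
       yield_gp = dist_spec("beta", shape1 = 24, shape2 = 89),
       yield_es_tier1 = dist_spec("beta", shape1 = 27, shape2 = 46),
       yield_es_tier2 = dist_spec("point", value = 0.35),
       yield_es_tier3 = dist_spec("beta", shape1 = 228, shape2 = 464))
}

#' Probabilistic sensitivity analysis
#'
#' Propagates parameter uncertainty through the cost-effectiveness engine:
#' for each joint draw from `specs` the diagnostic tree is rebuilt and its
#' expected cost, expected effectiveness and effective cost recomputed.
#' Draws whose expected effectiveness is not strictly positive are retained
#' in the per-draw table with an undefined (`NA`) effective cost and are
#' excluded from the effective-cost summary; their count is reported.
#'
#' @param tree_builder Function taking a named list of sampled parameter
#'   values and returning a valid `dx_tree`.
#' @param specs Named list of [dist_spec()] objects.
#' @param utility A [utility_params()] object held fixed across draws.
#' @param n Number of draws (>= 1).
#' @param seed Integer seed; fixed seeds reproduce the result exactly.
#' @return An object of class `dx_psa`: list with `draws` (per-draw data
#'   frame of sampled parameters and metrics), `summary` (mean, sd and
#'   2.5/97.5 percentiles per metric), `n_undefined_effective_cost` and
#'   `seed`.
#' @export
probabilistic_sensitivity <- function(tree_builder, specs, utility, n, seed) {
  stopifnot(is.function(tree_builder), inherits(utility, "dx_utility"))
  draws <- sample_parameters(specs, n, seed)
  metrics <- matrix(NA_real_, nrow = n, ncol = 3,
                    dimnames = list(NULL, c("expected_cost",
                                            "expected_effectiveness",
                                            "effective_cost")))
  for (i in seq_len(n)) {
    row <- as.list(draws[i, , drop = FALSE])
    tree <- tryCatch(tree_builder(row), error = function(e)
      stop("tree builder failed on draw ", i, " (",
           paste(sprintf("%s=%.6g", names(row), unlist(row)),
                 collapse = ", "), "): ", conditionMessage(e)))
    cost <- expected_cost(tree)
    eff <- expected_effectiveness(tree, utility)
    metrics[i, "expected_cost"] <- cost$expected_cost
    metrics[i, "expected_effectiveness"] <- eff$expected_effectiveness
    if (eff$expected_effectiveness > 0)
      metrics[i, "effective_cost"] <-
        cost$expected_cost / eff$expected_effectiveness
  }
  tab <- cbind(data.frame(draw = seq_len(n)), draws,
               as.data.frame(metrics))
  summarise <- function(x) {
    x <- x[!is.na(x)]
    if (!length(x))
      return(c(mean = NA_real_, sd = NA_real_, q2.5 = NA_real_,
               q97.5 = NA_real_))
    c(mean = mean(x), sd = stats::sd(x),
      q2.5 = unname(stats::quantile(x, 0.025)),
      q97.5 = unname(stats::quantile(x, 0.975)))
  }
  structure(list(draws = tab,
                 summary = t(apply(metrics, 2, summarise)),
                 n_undefined_effective_cost =
                   sum(is.na(metrics[, "effective_cost"])),
                 seed = as.integer(seed)),
            class = "dx_psa")
}

#' PSA preconfigured for a case-study strategy
#'
#' @param scenario `"1"`-`"4"` or `"ai"`.
#' @param n Number of draws.
#' @param seed Integer seed.
#' @param specs Distribution registry (default [case_dist_specs()]); names
#'   must be [case_params()] fields.
#' @param params Baseline registry for the non-sampled parameters.
#' @param utility Utility parameters (default [case_utility()]).
#' @param ai AI configuration for scenario `"ai"`.
#' @return A `dx_psa` object.
#' @export
psa_scenario <- function(scenario, n, seed, specs = case_dist_specs(),
                         params = case_params(), utility = NULL,
                         ai = ai_config(precision = params$ai_precision)) {
  scenario <- as.character(scenario)
  if (is.null(utility)) utility <- case_utility(params)
  unknown <- setdiff(names(specs), names(params))
  if (length(unknown))
    stop("spec name(s) not in the case-study registry: ",
         paste(unknown, collapse = ", "))
  builder <- function(draw) {
    args <- unclass(params)
    args[names(draw)] <- draw
    pa <- do.call(case_params, args)
    if (scenario == "ai") build_ai_tree(pa, ai) else build_scenario(scenario, pa)
  }
  probabilistic_sensitivity(builder, specs, utility, n, seed)
}

#' @export
print.dx_psa <- function(x, ...) {
  cat(sprintf("<dx_psa> %d draws (seed %d)\n", nrow(x$draws), x$seed))
  print(round(x$summary, 4))
  if (x$n_undefined_effective_cost > 0)
    cat(sprintf("  %d draw(s) with non-positive effectiveness excluded from the effective-cost summary\n",
                x$n_undefined_effective_cost))
  invisible(x)
}

#' @export
summary.dx_psa <- function(object, ...) object$summary
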