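---
title: "Cost-effectiveness of multi-tier diagnostic pathways"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cost-effectiveness of multi-tier diagnostic pathways}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(diagtree)
```

## The model

A multi-tier diagnostic workflow is represented as a rooted tree
$T = (N, E)$ with four node kinds.  *Decision* nodes are clinical
judgement points where an expert selects the next action; in practice
they carry a consultation fee and a consultation delay.  *Action* nodes
execute a diagnostic step — ordering a test — and carry the test's cost
and turnaround time.  *Result* nodes hold the dichotomous outcome of the
preceding test; the transition from a result onwards is always trivial
(a single child).  *Exit* nodes terminate the process, either because a
diagnosis was reached or because the options are exhausted.  Each edge
$(i, j)$ carries a transition probability $P_{ij}$, and the outgoing
probabilities of every internal node sum to one.  A decision-to-action
probability encodes protocol adherence (0/1 under a standard protocol);
an action-to-result probability is the test's *diagnostic yield* — the
fraction of all tested individuals with a positive result, which is a
population quantity distinct from sensitivity.

Recursion in a real diagnostic process ("test, review, test again") is
represented by explicit unrolling into a finite tree; cyclic structures
are rejected by `validate_tree()`, because the expected-cost recursion
below only terminates on acyclic structure.

### Expected cost

Writing $C_i$ for the direct cost at node $i$, the cumulative expected
cost obeys

$$EC^+_i = \begin{cases} C_i & \text{children}(i) = \emptyset \\
C_i + \sum_j P_{ij}\, EC^+_j & \text{otherwise,} \end{cases}$$

evaluated leaf-to-root; the root value is the expected total cost of the
whole process.  `expected_cost()` implements the recursion as an
explicit post-order traversal rather than call-stack recursion, so tree
depth is bounded only by memory.  The same recursion with turnaround
time (TAT) substituted for cost gives the expected TAT, which is valid
because expectation is linear along pathways.  Two independent checks
are built in and exercised by the test suite: exhaustive pathway
enumeration (`enumerate_paths()`; the root value must equal
$\sum_{\text{paths}} p \cdot \text{cost}$) and a Monte-Carlo cohort
walker (`simulate_cohort()`).

### Effectiveness and effective cost

Each root-to-exit pathway ends in an *outcome state* described by the
final result and the accumulated turnaround time
$TAT = \sum_{j \in \text{path}} T_j$ (decision-node consultation delays
included — the accumulation runs over all ancestors of the exit, not
only test nodes).  Its utility is

$$U(S) = \alpha \cdot EGU + (1 - \alpha)\, e^{-\lambda \cdot TAT},$$

where $\alpha \in [0,1]$ weighs diagnostic accuracy against timeliness
and $\lambda$ (per week) controls how fast utility decays with delay.
The expected gain in utility ($EGU$) of a final positive result is
$PPV \cdot U_{TP} + (1 - PPV)\, U_{FP}$, and of a final negative result
$NPV \cdot U_{TN} + (1 - NPV)\, U_{FN}$, with predictive values from the
final test's sensitivity and specificity at the disease prevalence.
The *expected effectiveness* of a strategy is the probability-weighted
sum of the pathway utilities, and the *effective cost* — the summary
metric — is expected cost divided by expected effectiveness.  The ratio
is only reported when effectiveness is strictly positive; otherwise an
explicit error is raised instead of an infinite or negative ratio.

Two predictive-value conventions are supported.  The default,
`pv_mode = "final_test"`, evaluates the final test at the baseline
prevalence.  The alternative, `"serial_bayes"`, updates the prevalence
with `posterior_after_negative()` across each preceding negative tier
result before forming the final predictive value.  The default was
chosen because it reproduces the case study's published behaviour (under
serial updating the deep-tier positive pathways carry strongly negative
gains and the AI-delegated pathway never overtakes the expert baselines),
and because it matches how test-performance tables are usually quoted —
per test at the indication's prevalence.  Pathways that exit without any
dichotomous result earn a configurable neutral gain (`no_result_egu`,
default 0) and still earn the timeliness term.

### AI delegation

`delegate()` rewrites an expert decision point into the AI-delegation
structure: an AI action node (cost and TAT 0 by default — the reference
table lists a zero AI decision time and no AI fee; both are
configurable) followed by two AI result nodes partitioned by the
confidence threshold $r^*$.  With probability $q = P(r \ge r^*)$ the
recommended test is ordered automatically, skipping the expert fee, and
its positive-result probability becomes the AI's *precision*
$P(\text{test positive} \mid \text{AI predicted positive})$.  With
probability $1 - q$ the pathway falls back to the expert decision,
unaffected by AI performance.  Design choices worth stating:

* **The automated branch is fully automated.**  By default
  (`automate_branch = TRUE`) decision nodes *inside* the automated
  subtree also lose their fee and consultation time, matching a gate
  whose downstream reviews are machine-ordered.  Keeping downstream
  expert reviews (and their fees) is available via
  `automate_branch = FALSE`; in the bundled case study that variant
  moves the cost-effectiveness crossover from about 0.41 to about 0.48.
* **Precision changes yield, not accuracy.**  Predictive values of the
  automated test still use the test's own sensitivity and specificity:
  the AI alters which patients receive the test (selection), not the
  assay's error rates.
* **Gate probability defaults to 1** in the case-study sweeps — the
  published delegation curves plot a single AI-mode pathway against the
  expert baselines without stating a population gate rate, which is the
  patient-conditioned reading ($r$ is fixed for a given patient, so
  $q \in \{0, 1\}$).  Population-level gates in $(0,1)$ are fully
  supported and sweepable.

`crossover_precision()` locates the smallest precision at which the
delegated tree's effective cost falls to the best baseline's.  It first
scans a 101-point grid to verify the objective is monotone
non-increasing (raising an error recommending a dense grid scan if not),
then bisects to a tolerance of $10^{-4}$, breaking ties toward the
smaller precision.

## The case study

The bundled case study compares four strategies for developmental delay
and multiple congenital anomalies (DD & MCA): (1) chromosomal microarray
(CMA) then gene panel (GP); (2) CMA, GP, then third-tier exome
sequencing (ES); (3) CMA then second-tier ES; (4) first-tier ES only —
plus the AI-delegated variant in which, after a negative CMA, an AI
predicts whether the GP will yield a diagnosis and orders it directly
when confident, falling back to strategy 3 otherwise.

Deterministic runs use the published point values: expert fee 165 and
consultation time 4 weeks at every human decision node; CMA 825 / 2
weeks, GP 1500 / 4 weeks, ES 4589.4 / 8 weeks; tier yields
$YD_0 = 0.1$ (CMA), $YD_1 = 0.11$ (GP), $YD_{2,1} = 0.37$,
$YD_{2,2} = 0.35$, $YD_{2,3} = 0.33$ (ES as first/second/third tier);
sensitivities and specificities 0.9068/0.9440 (CMA), 0.8960/0.9250
(GP), 0.9593/0.9933 (ES); prevalence 0.1665; reference AI precision
0.87.  Three of those choices deserve comment:

* **Terminal reviews are charged.**  A decision node whose only option
  is to exit still carries the expert fee and consultation time —
  nothing exempts the final review visit.  The sensitivity flag
  `free_exit_decisions` removes it.
* **Point values, not prior means.**  The GP yield's reference Beta(24,
  89) has mean ≈ 0.21, inconsistent with the published point value
  0.11; deterministic runs use the point values throughout and the Beta
  registry only feeds the probabilistic sensitivity analysis.  The GP
  cost is 1500, inside its quoted 1450–1750 range.
* **Node ids mirror the published workflow numbering** ("1", "2", …,
  with primes for AI-branch nodes), so pathways can be read against the
  figures; exits without a printed number use an "x" prefix.

With $\alpha = 0.5$, $\lambda = 0.03$ and symmetric unit utilities the
engine reproduces the published orderings: strategy 1 has the lowest
effective cost across the whole $\alpha$ grid, first-tier ES delivers
the highest expected effectiveness where accuracy dominates, the
delegated pathway's effective cost falls monotonically with precision,
and it overtakes both multi-tier expert baselines at a precision of
about 0.41 (bisection value 0.4143; with downstream reviews kept on the
automated branch, 0.48).

```{r crossover}
round(as.numeric(case_crossover(alpha = 0.5, lambda = 0.03)), 4)
```

## Probabilistic sensitivity analysis

`case_dist_specs()` carries the reference distributions: CMA cost
Gamma(2010, 2.44), GP cost Uniform(1450, 1750), ES cost Normal(4589.4,
45) truncated at zero, and Beta yields.  Two parameterisation choices
are documented assumptions, as the reference table does not state them:
the Gamma is shape/rate — mean $2010 / 2.44 \approx 823.8$, matching the
deterministic CMA cost to 0.15%, whereas shape/scale would put the mean
near 4904, contradicting every printed CMA cost — and the Normal is
mean/sd.  `probabilistic_sensitivity()` redraws the parameters jointly,
rebuilds the tree per draw and recomputes all three metrics; draws with
non-positive effectiveness are retained in the per-draw table with an
undefined effective cost, excluded from that metric's summary, and
counted.  Truncation is enforced by rejection with a cap of 1000
resamples per value.  Everything is reproducible from a single integer
seed.

Because expected cost is multilinear in the independently sampled costs
and yields, its Monte-Carlo mean equals the cost evaluated at the
distribution means up to sampling error — a calibration property the
test suite checks at 2,000 draws against a 3-standard-error band.

## What the random-tree generator emulates

`random_tree()` grows alternating decision–action–result tiers with
Dirichlet-distributed action choices, uniform costs (0–5000) and delays,
and geometric depth, emulating the *structure* of tiered work-ups for
property tests (normalisation, oracle agreement, linearity,
monotonicity).  It does not emulate correlated yields across tiers,
informative test performance, or realistic cost magnitudes, so passing
property tests establishes the algebra of the engine, not the clinical
realism of any particular tree.

## Numerical choices and verification sizes

Probability normalisation uses an absolute tolerance of $10^{-9}$
(inputs are hand-written decimals).  Oracle-agreement tests compare the
recursion against pathway enumeration on 1,000 generated trees at
relative tolerance $10^{-9}$; the cohort check uses 200,000 walks and a
3-standard-error band; predictive values are checked against an
expected-count contingency table on a 1,000-point grid at $10^{-9}$;
sampler moments use 100,000 draws.  Serialisation sorts keys and nodes,
so documents are byte-stable and round-trip exactly.

## Limitations

The engine covers finite, acyclic, dichotomous-result processes: no
Markov state transitions, no discounting or half-cycle corrections, no
utilities for continuous-valued test results (the schema reserves the
hook; the effectiveness module rejects numeric results), no correlated
parameter sampling, and no learning of patient-conditional transition
probabilities — personalised probabilities enter as user-supplied
parameters.  Costs and turnaround times vary widely across institutions;
the bundled values are one published configuration, not a
recommendation.
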