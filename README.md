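# diagtree

Cost-effectiveness analysis of multi-tier diagnostic pathways.

Rare-disease work-ups proceed in tiers — screen, targeted test,
broader sequencing — with an expert review between steps.  Which
sequence is worth its money depends on test costs, diagnostic yields,
turnaround times, and how much the patient values accuracy versus a
fast answer.  `diagtree` models such a workflow as a rooted
decision–action–result tree with transition probabilities and evaluates
it for clinicians, health economists and methods researchers comparing
tiered testing strategies, including workflows where an AI orders the
next test automatically when its confidence clears a threshold.

## The model in brief

With per-node cost $C_i$ and edge probabilities $P_{ij}$, the expected
cost of the process is the root value of the leaf-to-root recursion

$$EC^+_i = C_i + \sum_{j \in \mathrm{children}(i)} P_{ij}\, EC^+_j,$$

and the expected turnaround time (TAT) is the same recursion over node
delays.  Each root-to-exit pathway is scored by

$$U(S) = \alpha \cdot EGU + (1-\alpha)\, e^{-\lambda \cdot TAT},$$

where the expected gain in utility ($EGU$) weighs the final result by
the test's predictive values ($PPV \cdot U_{TP} + (1-PPV) U_{FP}$ for a
positive, $NPV \cdot U_{TN} + (1-NPV) U_{FN}$ for a negative).
Expected effectiveness is the probability-weighted sum of pathway
utilities, and the **effective cost** — the summary metric — is
expected cost divided by expected effectiveness.  An AI-delegated
decision point replaces the expert node with a confidence gate: above
the threshold the recommended test is ordered without the expert fee
and its positive probability is the AI's precision; below it the
pathway falls back to expert judgement.

## Worked example

The bundled case study covers four strategies for developmental delay &
multiple congenital anomalies (DD & MCA) built from chromosomal
microarray (CMA), gene panel (GP) and exome sequencing (ES):

```r
library(diagtree)

tr <- build_scenario(1)          # CMA, then GP after a negative CMA
tr
#> <dx_tree> 13 nodes (3 action, 3 decision, 3 exit, 4 result), root '1'
#>   scenario: scenario-1
#>   tests: cma, gp, es

cost_effectiveness(tr, case_utility(alpha = 0.5, lambda = 0.03))
#> <dx_cea>
#>   expected cost:          2620.66
#>   expected TAT (weeks):   16.40
#>   expected effectiveness: 0.7372
#>   effective cost:         3554.72
#>   pathways: 3
```

So the two-tier CMA+GP strategy costs \$2,620.66 in expectation, takes
16.4 expected weeks, and delivers 0.7372 units of effectiveness —
\$3,554.72 per unit.  The AI-delegation question — *how precise must an
AI that triages patients between GP and ES be before delegation is the
most cost-effective option?* — is answered by bisection over the
delegated tree:

```r
round(as.numeric(case_crossover(alpha = 0.5, lambda = 0.03)), 4)
#> [1] 0.4143
```

i.e. once the AI's precision exceeds about 0.41, the delegated pathway
undercuts both multi-tier expert-alone strategies per unit of
effectiveness.  Parameter uncertainty propagates through
`psa_scenario()`:

```r
psa_scenario(1, n = 500, seed = 42)
#> <dx_psa> 500 draws (seed 42)
#>                             mean       sd      q2.5     q97.5
#> expected_cost          2686.2774  81.5526 2550.3229 2826.7900
#> expected_effectiveness    0.7152   0.0081    0.6984    0.7312
#> effective_cost         3756.5225 120.5449 3540.0408 3970.6493
```

Trees are plain JSON documents (`read_tree()` / `write_tree()`;
fixtures under `inst/extdata/`), and a command-line front end wraps the
same functions:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "diagtree.R", package = "diagtree"))')" \
  cea inst/extdata/scenario1.json --alpha 0.5 --lambda 0.03
```

Subcommands: `validate`, `cost`, `simulate`, `cea`, `delegate`,
`crossover`, `casestudy`, `sweep`, `psa`.

See `vignettes/diagnostic-cost-effectiveness.Rmd` for the full model
description, parameter conventions and design decisions.

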