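Package: diagtree
Title: Cost-Effectiveness Analysis of Multi-Tier Diagnostic Pathways
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models multi-tier diagnostic workflows as rooted
    decision-action-result trees and evaluates them economically.  Expected
    cost and turnaround time are computed by a leaf-to-root recursion over
    transition probabilities; effectiveness combines predictive-value based
    utility of the final test result with an exponential penalty on
    diagnostic delay, and their ratio gives the effective cost of a
    strategy.  Supports rewriting an expert decision point into an
    AI-delegated gate (automated test ordering above a confidence
    threshold), locating the AI precision at which delegation becomes the
    most cost-effective option, parameter sweeps, probabilistic sensitivity
    analysis over parameter distributions, and a bundled case study of
    tiered genetic testing (chromosomal microarray, gene panel, exome
    sequencing) for developmental delay and multiple congenital anomalies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
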