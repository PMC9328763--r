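Package: replidyn
Title: Replication Dynamics from Single-Molecule DNA Fiber Assays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying DNA replication dynamics in cell-free
    (Xenopus egg extract) systems. Implements a stochastic single-fiber
    replication simulator (Poisson origin licensing, early/late firing
    clusters, bidirectional fork progression with passive replication),
    the DNA combing measurement calculus (replication eyes, fork counts,
    replicated fraction, fork density, eye lengths, eye-to-eye distances,
    origin positions), closed-form nucleation-growth (KJMA) references,
    incorporation-kinetics normalization with four-bin S-phase
    partitioning, corrected-total-fluorescence nucleus quantification,
    and depleted/mock ratio statistics (one-sample t, exact Wilcoxon
    signed-rank and Mann-Whitney tests, co-IP enrichment filtering).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
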