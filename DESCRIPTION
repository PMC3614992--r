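Package: chronoq
Title: Temporal Ordering of Expression Samples by Tabular Q-Learning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Recovers a pseudo-temporal ordering of multi-dimensional
    biological samples (bulk or single-cell expression profiles) by casting
    the ordering task as a maximum-adjacent-similarity Hamiltonian path under
    a successor-dominance validity constraint, and solving it with a tabular
    Q-learning agent over a tree-shaped episodic environment. Includes
    Pearson-correlation gene filtering against survival times or known
    sampling times, an exhaustive backtracking oracle certifying optimal
    valid orderings on small instances, the samples-misplacement-degree (SMD)
    statistic for scoring orderings against known time points, a synthetic
    data generator with a known latent trajectory, tab-delimited readers and
    writers for all inputs and outputs, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr,
    SummarizedExperiment,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'io.R'
    'preprocess.R'
    'similarity.R'
    'qlearning.R'
    'solve.R'
    'oracle.R'
    'evaluation.R'
    'fixtures.R'
    'simulate.R'
    'cli.R'
    'chronoq-package.R'
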