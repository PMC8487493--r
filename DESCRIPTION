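Package: neurodiverge
Title: Brain Gene-Expression Divergence Analysis for Reinforcement Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for analysing brain gene-expression divergence
    between ancestral (allopatric) and reinforced (sympatric) populations of a
    species undergoing cascade reinforcement. Implements count filtering and
    TMM normalization, negative-binomial likelihood-ratio differential
    expression with empirical-Bayes dispersion shrinkage, keyword-based
    identification of candidate synaptic-transmission genes, neighbor-joining
    expression-divergence trees with randomization tests, differential
    expression count-ratio permutation tests, weighted gene co-expression
    network analysis (soft thresholding, topological overlap, dynamic module
    detection, eigengene-trait correlation), and synaptic-pathway
    concentration randomization tests. Ships a synthetic-data generator that
    emulates the two-by-two geography-by-sex study design for end-to-end
    validation and parameter-recovery testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    ape,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    withr,
    yaml,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
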