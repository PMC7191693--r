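Package: ecprop
Title: Enzyme Function Annotation by Label Propagation on Domain-Composition Graphs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Annotates proteins with Enzyme Commission (EC) numbers by linking
    proteins through the Jaccard similarity of their InterPro domain
    compositions and propagating neighbor labels with similarity-weighted
    votes. Provides an inverted-index domain-similarity graph over annotated
    proteins, single-hop weighted label propagation with ranked candidate
    annotations, readers for a native annotation table and InterProScan
    tab-separated output, a hierarchical (level-wise) EC evaluation protocol
    with macro-averaged metrics and annotation coverage, leave-one-out and
    stratified k-fold validation modes, threshold sweeps, and a synthetic
    fixture generator with controlled domain-sharing structure. A thin
    command-line interface exposes the build, annotate, evaluate, sweep,
    cross-validation and simulation drivers.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    optparse,
    igraph
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
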