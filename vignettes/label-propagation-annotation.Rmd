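---
title: "Annotating enzyme function by label propagation over domain-composition graphs"
author: "ecprop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotating enzyme function by label propagation over domain-composition graphs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecprop)
```

## The model

`ecprop` treats enzyme function annotation as inference on a similarity
graph. Each reference protein is a node carrying two things: its *domain
composition* — the unordered set of unique InterPro signatures found in its
sequence — and its function labels, typically EC numbers. Two proteins are
implicitly linked whenever their compositions overlap, and the link weight
is the Jaccard similarity of the two sets,
$W_{u,v} = |A \cap B| / |A \cup B|$. The Jaccard ratio, rather than the
raw shared-domain count, is used because the count ignores composition
size: sharing 2 of 5 distinct domains is a far stronger statement than
sharing 2 of 11.

A query composition $u$ is annotated in a single hop: its neighbors
$N(u)$ are retrieved, each neighbor $v$ votes with weight $W_{u,v}$ for
every label it carries, and candidates are ranked by the weighted
frequency
$$f^i_u = \frac{\sum_{v \in N(u)} W_{u,v}\,\delta(v, i)}
               {\sum_{v \in N(u)} W_{u,v}},$$
with $\delta(v, i) = 1$ iff $v$ carries label $i$. The denominator is
constant per query, so the cumulative-weight and normalized rankings always
agree; the normalized score is reported because it is comparable across
queries. There is no iterative re-propagation and no per-class model
fitting: once the graph is built, annotation is a neighborhood vote.

The method's central assumption is that domain composition is predictive
of enzyme function. It will fail exactly where that assumption fails: for
compositions mapping to many ECs (the many-to-many pathology), for
proteins whose function is determined by residues rather than domain
architecture, and for queries with no composition overlap at all (the
no-prediction case, which is reported as reduced coverage rather than
hidden).

## Parameters that matter

* `minSim` (default **0.3**, dimensionless Jaccard units): minimum
  similarity for a neighbor to vote. Lower values admit weakly linked
  neighbors, raising coverage but adding false positives; the default is
  the knee of the accuracy/coverage trade-off in practice. The evaluation
  grid spans 0.05–0.5 because coverage collapses beyond 0.5.
* `maxSim` + `strictMax` (default 1, inclusive): the upper similarity
  bound. `strictMax = TRUE` with `maxSim = 1` excludes exactly the
  Jaccard-1 neighbors — proteins with the *identical* composition — which
  removes trivial direct mappings when the query is itself part of the
  reference set. The comparison is an exact `<` on double-precision
  ratios of small integers; no epsilon is involved.
* `topK` (default 1 in the annotation drivers): how many ranked labels to
  report. The evaluation protocol always scores the single top label;
  `propagate()` itself returns the full ranking by default because the
  ranked tail is what makes a prediction explainable.
* Self-exclusion is by accession: batch annotation always removes the
  query's own accession from its neighbor pool, which is precisely the
  leave-one-out discipline used in validation.

## EC codes, incomplete labels and level-wise scoring

EC numbers are handled as canonical four-component strings with `-` for
unresolved components (`"3.1"` parses to `"3.1.-.-"`). Reference proteins
with incomplete codes stay in the graph and propagate their labels as-is —
they are informative at the levels they do resolve. At evaluation time both
truth and prediction are truncated to each level $k \in \{1,2,3,4\}$; a
label not resolved at level $k$ truncates to an undefined marker that never
matches anything. How incomplete *predictions* should be scored at deeper
levels is genuinely underdetermined; the never-matching convention is this
package's choice, made because it cannot inflate accuracy.

Two further scoring conventions are deliberate:

* **Accuracy denominator.** Accuracy is computed over *covered* proteins
  (those with at least one prediction) by default, with coverage $M/T$
  reported alongside; only this reading lets accuracy stay high while
  coverage drops as `minSim` grows. A `coveredOnly = FALSE` mode counts
  every non-prediction as wrong.
* **Macro metrics.** The class set is the set of labels present in the
  ground truth of the evaluated set. A class never predicted gets
  precision 0 (and F1 0) instead of an undefined division. Recall is
  $|A \cap P| / |A|$ — the standard definition, chosen over the
  occasionally seen $|A \cup P|/|A|$ variant, which is not a rate (it can
  exceed 1) and is inconsistent with the matching precision formula.
* **Multi-EC test proteins** are excluded by default (single-EC
  evaluation); an inclusive mode scores a hit when the top prediction
  matches any of the truths.

## The synthetic generator

`generateFixture()` emulates the statistical structure of curated enzyme
annotation data with a clique-based generative model: the domain
vocabulary is split into disjoint per-class cliques, each protein samples
its composition inside its home clique, and its label equals the home
class with probability `classPurity` (otherwise uniform over classes).
Purity is thus one dial from perfectly separable (1.0: label propagation
must achieve perfect accuracy among covered proteins) to pure noise (0.0:
accuracy must concentrate at $1/k$). The defaults encode the pathology
rates of real curated data: 4.3% single-domain proteins, 5.7% multi-EC
proteins, 15% incomplete EC codes, and six classes mirroring the six EC
main classes; `classPurity = 0.9` and compositions of 2–6 domains from
25-domain cliques give graphs that are informative but not trivial.

What the generator does *not* emulate: real InterPro signature frequency
distributions (which are heavy-tailed), real EC class imbalance, and
overlapping cliques (real domains are shared across functions). Passing
tests on these fixtures therefore demonstrate the correctness of the
machinery and its statistical behavior under controlled signal, not
field performance on UniProtKB-scale data.

## Numerical and design choices

* **Edges are never materialized.** All neighbor queries run through an
  inverted domain→protein index; intersection sizes come from a single
  `tabulate()` over the index hits, and the union size follows from
  $|A| + |B| - |A \cap B|$. Weights are exact ratios of small integers in
  double precision, so threshold comparisons can be exact.
* **Determinism.** Neighbor lists sort by descending weight with ties
  broken by ascending accession; rankings sort by descending cumulative
  weight with ties broken by ascending label string (a top-rank tie is
  flagged). All generator and fold-split randomness flows through one
  explicit seed, and the stratified k-fold shuffle is applied to
  class-wise *sorted* accession lists, making fold membership invariant
  under input row permutation.
* **Degenerate inputs.** Empty compositions are rejected at parse and
  query time (a protein must carry at least one signature to enter a
  graph); queries with no overlap produce an empty ranking, not an error;
  per-query failures in batch mode are collected and summarized rather
  than fatal.
* **Problem sizes.** The test suite checks oracle equivalence (brute-force
  pairwise scan, direct formula evaluation, confusion-matrix metrics) on
  random graphs up to 200 nodes, and statistical behavior on fixtures of
  2,000–10,000 proteins, sizes at which every property is sharp while the
  whole suite runs in about a minute.

## A complete round trip

```{r example}
rows <- generateFixture(nProteins = 150, seed = 42)
g <- buildGraph(rows)
g
report <- evaluateLOO(g, rows, minSim = 0.3)
report
```

```{r sweep}
sweep <- thresholdSweep(g, rows, minSims = seq(0.05, 0.5, by = 0.05))
head(sweep[sweep$level == 1, c("minSim", "maxSimMode", "accuracy", "coverage")])
```

## Known limitations

* Single-hop propagation only: labels reach a query exclusively from
  direct composition neighbors; proteins connected only transitively
  contribute nothing.
* Annotation coverage is bounded by composition overlap with the
  reference set; novel domain architectures are unannotatable by design.
* EC codes are validated for well-formedness, not for existence in the
  official enzyme list.
* The binary enzyme/non-enzyme mode shares all machinery with the EC mode
  but treats labels as opaque strings; it performs no level-wise scoring.
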