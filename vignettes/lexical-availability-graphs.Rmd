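---
title: "Lexical availability graphs: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lexical availability graphs: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lexavail)
```

## The model

A lexical availability task asks informants to produce, under a time
limit, as many words as possible for a cue category. The produced chain is
not a random sample of the lexicon: responses arrive in semantically
coherent runs, and consecutive words tend to be associates. `lexavail`
operationalises this with the **lexical availability graph** (LAG): a
directed graph whose nodes are the word types of the sample and whose
edges are the contiguous ordered pairs of the chains, each edge weighted
by the number of informants who produced that pair. Because chains are
de-duplicated per informant before construction, a pair can occur at most
once per chain, so "number of chains containing the pair" and "number of
informants producing it" coincide — an identity the test suite asserts
rather than assumes. Self-loops are impossible for the same reason.
Reverse pairs (a, b) and (b, a) are distinct edges, and the graph may be
disconnected.

The working hypothesis the toolkit is built to examine is that LAGs are
**small worlds with anchored modules**: clustering far above a matched
random baseline, path lengths comparable to it, and modularity communities
organised around high-centrality *anchor words* that harness retrieval of
their semantic field.

## Conventions that matter

Several quantities have competing definitions in the literature; the
package fixes them as follows.

**Density and clustering are directed.** Density is E/(N(N−1)). The
clustering coefficient of a vertex v is the density of the directed
subgraph spanned by its *pooled* in- and out-neighbours: with k
neighbours and r directed edges among them, r/(k(k−1)). This
back-calculates exactly against the three published reference densities
(240 nodes / 942 edges → 0.016; 431/918 → 0.005; 30/67 → 0.077), which is
how the convention was confirmed. Nodes with k < 2 contribute 0 and are
included in the graph mean by default; `mean_clustering(...,
include_low_degree = FALSE)` averages only over k ≥ 2 nodes, since
tool-specific handling of low-degree vertices varies and cannot always be
recovered from published tables.

**Distances are hop counts.** Edge weights never enter path computations:
path length is the number of edges traversed. Directed distances are the
default; every path-based report also carries an undirected (symmetrized)
mode because some graph tools silently symmetrize, and published
diameters do not always say which convention produced them. Averages and
diameters are taken over *reachable ordered pairs only*, with the reached
fraction reported alongside, so disconnection is visible rather than
fatal. A node that reaches nothing has eccentricity and closeness 0;
harmonic closeness uses 1/∞ = 0 and so needs no special case.

**Rankings are deterministic.** Every ranking (centrality top-k lists,
availability tables, community ordering, anchor selection) breaks ties
lexicographically. Eccentricity ranks ascending — lower eccentricity means
more central. `top_central()` exposes a generic `min_value` filter rather
than hard-coding any outlier cut-off, because published cut-offs of the
form "values over 1" are tool-specific and their exact semantics are not
recoverable.

**Modularity runs on the undirected weighted projection.** Reciprocal
edge weights are summed, then Louvain greedy maximisation is applied; the
graph stays directed everywhere else. The reported score is always
re-evaluated by `modularity_score()` — a direct implementation of weighted
Newman modularity — independently of the optimiser, and the two are
cross-checked in tests against both a brute-force enumeration of all
partitions (on 8-node fixtures) and an independent library evaluation.
The resolution parameter defaults to 1 (the classical quality function)
and a seed is mandatory: published modularity values from single
optimiser runs are seed- and data-dependent, so they are treated as
context, not as reproduction targets.

## The availability index

The availability of word j combines frequency and earliness:

$$D(P_j) = \sum_{i=1}^{n} e^{-2.3\,\frac{i-1}{n-1}}\; \frac{f_{ji}}{I_1}$$

with \(f_{ji}\) the number of informants producing word j at position i,
\(I_1\) the informant count, and n the maximal position. The decay
constant 2.3 is the field's convention; it is configurable but never
silently changed. Properties that follow from the formula — D = 1 for a
word produced first by everyone, D bounded by relative frequency with
equality only at position 1, monotone growth under earlier placement —
are all asserted in the suite with closed-form expected values (e.g.
(1 + e^(−2.3))/2 on the symmetric two-chain fixture).

Two interpretive choices were genuinely open:

- **n is sample-wide** (the longest chain for the prompt), the standard
  convention of the classical index; the phrase "maximal position reached
  by the word" admits a per-word reading, so `per_word_n = TRUE`
  implements that alternative explicitly rather than leaving it
  unobtainable.
- **n = 1 degenerate case**: the exponent is taken as 0 (its limit), so D
  reduces to relative frequency.

Positions are recompacted to 1..L after editing removes duplicates, since
the index formula assumes gap-free ranks.

## Null models and the small-world verdict

The baseline for "is this clustering high?" is the uniform **G(n, m)
simple directed graph**: exactly the observed node and edge counts, m
ordered pairs sampled without replacement, no self-loops. Exact matching
was chosen over approximate density matching because it is stricter and
removes one source of variance; a Bernoulli G(n, p) variant
(`random_lag_gnp()`) is provided for sensitivity analysis. In this model
the expected clustering coefficient equals the density m/(n(n−1)) up to
O(1/n) terms, a convergence the suite checks within three Monte-Carlo
standard errors at n = 236.

`small_world_report()` draws a seeded ensemble (default 50 replicates;
each replicate's seed is derived as `seed·1000 + r` so runs are
bit-reproducible), reports per-metric means and standard deviations, and
computes observed/random ratios. The verdict flag is an explicit,
configurable rule — clustering ratio ≥ 5 and path ratio ≤ 2 by default —
rather than a hidden constant, because the underlying empirical claim is
qualitative (clustering an order of magnitude above random, paths
comparable).

## What the synthetic generator emulates

`make_lexicon()` + `simulate_chains()` produce corpora with the
statistical structure the analysis presumes, so every stage is testable
without access to raw learner data (which such studies typically do not
publish):

- a **modular lexicon**: disjoint semantic clusters, default 5 × 12 words;
- **graded availability**: within a cluster, retrieval weights decay
  geometrically (ratio 0.75, a Zipf-like profile) from an anchor word
  whose weight is boosted ×3 over the next member — mimicking the
  concentration of production on a few high-availability items;
- a **clustered retrieval walk**: words are drawn without replacement
  proportionally to weight within the current cluster; after each word
  the walk switches to a fresh cluster with probability `p_switch`
  (default 0.08) and always when the cluster is exhausted — the two
  switching mechanisms of the clustering/switching account of fluency —
  and with probability `erratic_rate` (default 0.03) jumps to a uniformly
  random unused word, modelling chance adjacencies;
- **chain lengths** from a shifted negative binomial (mean 14, size 6,
  minimum 1), since fluency studies report time limits rather than length
  distributions; the defaults put the bulk of lengths in the 5–25 range
  typical of two-minute tasks with ~100 informants.

The planted partition, anchors and weights are exposed by
`ground_truth()`, and recovery is scored with the package's own adjusted
Rand index (cross-checked against an independent implementation in
tests).

What the generator does **not** emulate: the open-ended vocabulary of
real informants (real fluency graphs have hundreds of node types, most
produced by a single informant; the synthetic lexicon is closed at 60
words), inter-informant proficiency differences, response-time structure,
and cross-language interference. Two consequences matter when reading the
test results. First, the closed vocabulary makes the synthetic LAG much
denser (≈0.15–0.2) than real LAGs (≈0.005–0.016), which compresses the
clustering ratio against the matched null: the ratio stays robustly above
1 but cannot reach the order-of-magnitude gap real graphs show, because
the null's clustering equals the (high) density. A passing suite
therefore demonstrates correct mechanics and qualitative structure, not
the full quantitative small-world contrast of real data. Second, planted
recovery being near-perfect reflects the generator's clean block
structure; real semantic communities are fuzzier.

## Numerical and engineering choices

- Graphs are held as `igraph` objects inside a light S3 wrapper; all
  metrics with contested definitions (clustering, closeness variants,
  modularity evaluation, the availability index) are computed by the
  package's own code, and everything is validated against brute-force
  oracles (Floyd–Warshall distances, shortest-path-counting betweenness,
  exhaustive neighbourhood enumeration) on randomized small graphs.
- Adjacency work uses dense logical matrices — exact and fast at the
  scale of fluency graphs (≤ a few thousand nodes).
- All randomness flows through explicit integer seeds (|seed| < 2³¹);
  sub-streams are derived arithmetically so pipeline stages are
  independently reproducible, and reports are bit-identical under a fixed
  seed.
- Pruning keeps edges with weight strictly above the threshold (the
  threshold is the *maximum removed weight*), then optionally drops
  isolated nodes; it is a pure function and monotone in the threshold.
- Degenerate inputs are defined, not errors, wherever a limit convention
  exists: single-word chains (a node, no edges), n = 1 availability,
  empty pruned graphs, unreachable nodes. Density and path statistics on
  fewer than 2 nodes are errors, as no convention exists.
- Test problem sizes are chosen to exercise the asymptotic regime while
  keeping the default suite fast: exhaustive oracle comparisons on 200
  random graphs of ≤ 8 nodes, ensemble checks at the published 236-node
  scale, and 20-seed medians for generator-recovery properties.

## Known limitations

- The pooled-neighbourhood directed clustering coefficient is one of
  several directed generalisations; values are not comparable to
  triangle-based transitivity without recomputation.
- Louvain is a greedy heuristic: the returned partition is
  seed-deterministic but not guaranteed optimal (the suite verifies
  optimality only on small brute-forced fixtures).
- Editing is deliberately conservative: no lemmatization, no automatic
  spelling correction, no singular/plural merging — only what an explicit
  user-supplied table requests. This mirrors hand-edited availability
  corpora and keeps the node inventory auditable.
- The availability index treats the sample aggregate; informant-level
  variation is out of scope.
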