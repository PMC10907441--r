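# lexavail

Network analysis of semantic fluency data through **lexical availability
graphs** (LAGs).

In a lexical availability (fluency) task, informants write down, under a
time limit, as many words as they can for a cue category ("animals",
"countryside", ...). Each informant's ordered response chain traces a walk
through their mental lexicon. `lexavail` aggregates those chains into a
directed, integer-weighted graph — an edge `a -> b` for every contiguous
pair, weighted by the number of informants who produced it — and provides
the full analysis toolkit used in psycholinguistic studies of the L1/L2
mental lexicon:

- **Corpus editing**: within-informant repetitions removed (first
  occurrence kept), multi-word responses hyphenated (`fresh air` →
  `fresh-air`), table-driven spelling correction, case folding.
- **Graph construction and pruning**: build the LAG; optionally remove all
  edges of weight ≤ *t* (keeping only associations shared by ≥ *t*+1
  informants) and drop the resulting isolated nodes.
- **Structural metrics** with directed conventions: density
  *E*/(*N*(*N*−1)); the clustering coefficient of a vertex *v* as the
  density *r*/(*k*(*k*−1)) of the subgraph spanned by its *k* pooled
  in/out-neighbours; hop-based shortest paths, diameter and eccentricity
  with explicit handling of disconnection.
- **Centralities**: degree, weighted degree, eccentricity, closeness,
  harmonic closeness, betweenness; deterministic top-*k* rankings and
  ranking-overlap (Jaccard) comparison across measures.
- **Communities**: Louvain modularity on the undirected weighted
  projection, with anchor-word cluster tables (the anchor is the
  highest-degree member of each community).
- **Availability index**: the classical positional-decay index

  *D(P<sub>j</sub>) = Σ<sub>i=1..n</sub> e<sup>−2.3 (i−1)/(n−1)</sup>
  f<sub>ji</sub> / I<sub>1</sub>*,

  where *f<sub>ji</sub>* counts informants producing word *j* at position
  *i*, *n* is the maximal position in the sample and *I*<sub>1</sub> the
  informant count. A word produced first by everyone scores exactly 1.
- **Null models**: uniform G(*n*, *m*) simple random digraphs matched to
  the observed node and edge counts, with a small-world report (observed
  vs. ensemble clustering, path length and diameter, and an explicit
  verdict rule).
- **Synthetic generator**: modular lexicons with availability-graded
  anchor words, traversed by a within-cluster walk with stochastic cluster
  switching and a small erratic-jump rate — planted ground truth included,
  so community and anchor recovery can be scored end to end.

## Worked example

```r
library(lexavail)

bundle <- lag_demo(seed = 1, null_replicates = 30)
bundle$lag
#> <lag> prompt: synthetic  nodes: 60  edges: 693
bundle$metrics
#> <metrics_summary> (directed paths)
#>   nodes 60  edges 693  density 0.196
#>   mean clustering 0.386  avg path 2.009  diameter 3  reachable 1.000
bundle$small_world
#> <small_world_report> 30 matched G(n,m) replicates
#>   observed: clustering 0.386  avg path 2.009  diameter 3
#>   random:   clustering 0.196  avg path 1.887  diameter 3.03
#>   ratios: clustering 1.97  path 1.06  -> small world: FALSE
bundle$partition
#> <community_partition> 5 communities, modularity 0.656
#>   sizes: 12, 12, 12, 12, 12

head(bundle$availability, 3)
#>   rank   word availability total_frequency max_position
#> 1    1 c02w01    0.3960529              50           37
#> 2    2 c03w01    0.3667368              50           23
#> 3    3 c02w02    0.3027966              41           34
```

The demo simulates 100 informants over a 5-cluster × 12-word lexicon and
runs the whole pipeline (including a weight-2 pruning pass). The planted
structure is recovered exactly: the five cluster anchors occupy the top
five degree ranks (`c01w01 ... c05w01`, total degree 33 each), the Louvain
partition matches the planted one (adjusted Rand index 1.0), and all five
anchors are identified as community anchors. The clustering coefficient
sits well above the matched random baseline (0.386 vs. 0.196) while the
average path length stays comparable (2.01 vs. 1.89) — the qualitative
small-world signature, although at this vocabulary size (60 words) the
graph is too dense for the clustering ratio to reach the order-of-magnitude
gap seen in real fluency graphs with several hundred node types.

For real data, start from `read_chains()` (long CSV/TSV
`informant_id,prompt,position,word`, or one chain per line) and
`run_pipeline()`, which writes all tables as CSV/JSON plus GEXF/GraphML
exports readable by Gephi.

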