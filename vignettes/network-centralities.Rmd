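---
title: "Centrality analysis of directed and weighted biological networks"
author: "netCentral"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Centrality analysis of directed and weighted biological networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netCentral)
```

## The problem

Protein-protein interaction, signalling and metabolic networks are static
maps of dynamic processes. Even without simulating the dynamics, a node's
position in the map carries information: hubs, relays and bottlenecks are
candidate regulators and candidate drug targets. Centrality indices
quantify that position, each from a different angle. This package computes
a comprehensive suite of them — degree, eccentricity, closeness, radiality,
centroid value, stress, betweenness, eigenvector, bridging, edge
betweenness, plus the network-level diameter and average distance — on
undirected, directed and weighted graphs, and joins the ranking with
experimental per-node measurements such as expression or phosphorylation
levels.

Two modelling choices drive everything else:

* **Direction.** In signalling and metabolic networks an edge has a
  natural direction (the flux of information or matter). Computing indices
  on the directed graph can rank nodes very differently from the
  undirected view: a node that relays many undirected paths may relay none
  once directions are respected, and vice versa. `compareModes()` makes
  this contrast explicit.
* **Weights as distances.** When edges carry a positive attribute
  interpreted as a *distance*, shortest paths minimise total attribute
  cost rather than hop count. On the bundled `weightedTriangle()` (edges
  A–B = 2, B–C = 3, A–C = 7) the unweighted distance from A to C is 1, but
  the weighted shortest path runs through B at cost 2 + 3 = 5, beating the
  direct edge's 7. Attributes that measure *strength* instead — a reaction
  speed, an interaction confidence — mean the opposite: the higher the
  value, the closer the nodes. `transformWeights(g, "strength")` takes
  reciprocals so that strong edges become short ones.

## The shortest-path machinery

All distance-based indices sit on one engine: single-source shortest
paths with path counting. Unweighted graphs use breadth-first search;
weighted graphs use Dijkstra's algorithm (weights must be strictly
positive, which Dijkstra requires). For each source $s$ the engine
produces distances $d(s,v)$, the number $\sigma_{sv}$ of distinct shortest
paths, and the predecessor sets that span the shortest-path DAG.

Stress and betweenness accumulate over that DAG in the standard dependency
recursion: for betweenness each target contributes
$\sigma_{sv}/\sigma_{sw}(1+\delta(w))$ to its predecessors; for stress the
analogous recursion carries whole path counts instead of fractions, so
stress(v) counts shortest paths through $v$ while betweenness(v) sums the
*fraction* of each pair's paths through $v$ — hence stress ≥ betweenness
node by node. Edge betweenness credits the same fractional flow to the
edge traversed. Pairs are unordered for undirected networks and ordered
for directed ones, and endpoints never count toward their own paths.

### Numerical choices

* **Tie tolerance.** On real-valued weights, two path costs are merged as
  equal when $|a-b| \le 10^{-9}\max(1,|a|,|b|)$. Path counting needs an
  explicit rule; a strict equality would split ties created by floating-point
  summation order.
* **Deterministic accumulation order.** The dependency recursion processes
  vertices by decreasing distance with ties broken by node index, rather
  than by the raw BFS/Dijkstra finalisation order. This makes a weighted
  run with all weights equal to 1 *bitwise identical* to the unweighted
  run, index by index — a property the test suite asserts with
  `identical()`, not a tolerance.
* **Unreachable pairs.** Disconnected networks are the norm in interaction
  data. Unreachable pairs carry distance $\infty$ and are excluded from
  every sum, mean and maximum, so all indices stay finite; a node that
  reaches nothing scores 0 for eccentricity, closeness and radiality.
* **Self-loops and parallels.** Self-loops never lie on a shortest path
  between distinct nodes and are excluded from every index (degree excludes
  them by default behind a flag). Parallel edges collapse to the minimum
  weight before computation; the file readers additionally reject duplicate
  edges whose weights disagree, because silently keeping one of them would
  change shortest paths.

## Index conventions

The suite follows the conventions in which larger always means more
central where a reciprocal makes that possible:

| index | definition | notes |
|---|---|---|
| degree | incident edges | directed: in, out, total |
| eccentricity | $1/\max_w d(v,w)$ | raw variant behind a flag |
| closeness | $1/\sum_w d(v,w)$ | over the reachable set |
| radiality | $\sum_w (\Delta + 1 - d(v,w)) / (n-1)$ | $\Delta$ = finite diameter |
| centroid value | $\min_{w \ne v} [\gamma_v(w) - \gamma_w(v)]$ | $\gamma_v(w)$ = #nodes strictly closer to $v$ |
| stress | #shortest paths through $v$ | endpoints excluded |
| betweenness | $\sum_{s \ne v \ne t} \sigma_{st}(v)/\sigma_{st}$ | unnormalized; flag to normalize |
| eigenvector | principal eigenvector of adjacency | power iteration, norm 1 |
| bridging | betweenness $\times\ \psi(v)$ | $\psi(v) = \frac{1/d(v)}{\sum_{i \in N(v)} 1/d(i)}$ |
| edge betweenness | per-edge fractional flow | endpoint pairs included |

Directed graphs measure distances along outgoing edges by default; the
`orientation = "in"` flag transposes the view, because whether "central"
means *reaches many* or *is reached by many* depends on what the edges
model. Weighted eigenvector centrality uses the weighted adjacency, with a
`topologyOnly` flag for the 0/1 matrix, since which variant a study wants
depends on whether the weights are comparable across edges.

### Power iteration details

The iteration runs on the unit-diagonal-shifted matrix $A + I$. The shift
leaves every eigenvector unchanged while making the leading eigenvalue
strictly dominant in modulus, so bipartite graphs (whose spectrum is
symmetric, $\pm\lambda_1$) converge instead of oscillating. Convergence is
declared when successive normalised iterates differ by less than $10^{-10}$
in max-norm; after 10,000 iterations without convergence the function
raises an error rather than returning a half-converged vector. That can
still happen legitimately: on a directed acyclic graph the adjacency is
nilpotent and mass drains toward sinks at a rate too slow for the
tolerance, which is reported, not masked.

## Comparing directed and undirected views

`compareModes(g, index)` computes one index both ways (directions dropped
via `asUndirected()`, which collapses antiparallel duplicates to the
minimum weight — the choice that preserves shortest-path semantics), then
reports per-node value pairs, ranks, rank shifts, the Spearman rank
correlation, and a quadrant label: high/high, high/low, low/high, low/low
relative to each mode's mean. The discordant quadrants are the interesting
ones — nodes whose biological interpretation flips with the direction
model.

"High" is *at or above* the mean (a closed boundary, so the rule is
deterministic and a constant vector classifies cleanly), with one
exception: an all-zero vector classifies every node low. The exception
matters because a direction flip can zero an entire stress vector — on the
3-node chain with both arcs pointing into B, directed stress is zero
everywhere — and calling a zero-stress node "high" because 0 ≥ mean(0)
would hide exactly the discordance the comparison exists to find.

## Integrating experimental data

`classifyNodes()` reproduces a boolean result panel: each selected
centrality and each experimental attribute is cut at a per-variable
threshold (mean, median, or a fixed `value:x`), high meaning ≥ threshold.
Nodes missing a measurement are unclassified *for that variable only* —
partial omics coverage is the norm and should not evict a node from the
whole report. `queryNodes()` evaluates conjunctions
(`"betweenness:high AND expression:high"`); unclassified nodes never
match, and adding a conjunct can only shrink the result. The query
language is AND-only by design, mirroring a result-panel workflow where
each query expresses one joint hypothesis.

```{r example}
g <- weightedTriangle()
res <- computeCentralities(g, c("betweenness", "closeness", "network"))
centralityValues(res$network)

at <- AttributeTable(data.frame(expression = c(4.2, 9.7, 8.1)),
                     ids = c("A", "B", "C"))
rep <- classifyNodes(res[c("betweenness", "closeness")], at, rule = "mean")
queryNodes(rep, "betweenness:high AND expression:high")
```

## The synthetic-data generator

`randomAnnotated()` produces the package's test and benchmark inputs: an
Erdős–Rényi graph (edge probability `p`) or a preferential-attachment
graph (`m` edges per arriving node, degree-proportional with +1
smoothing), optional random edge directions, optional log-normal edge
distances (meanlog 0, sdlog 0.5 — concentrated near 1 with a heavy right
tail, the shape of empirical interaction distances), and a node attribute
table with normal `expression` (mean 8, sd 2, a log2-intensity scale) and
`phosphorylation` (mean 0, sd 1, a log-ratio scale) columns. Every draw
comes from R's generator seeded with the mandatory `seed`, so a given
specification reproduces byte-identical files.

What the generator deliberately does **not** emulate: degree-correlated
attribute values (real expression correlates with connectivity),
module/community structure, hub-biased measurement dropout, or correlated
noise between attributes. Tests passing on these fixtures therefore
demonstrate algorithmic correctness and determinism, not robustness to
the sampling biases of real interactome data.

## Problem sizes and verification

The package's algorithms are verified against independent oracles rather
than against themselves: a cubic-time all-pairs relaxation
(Floyd–Warshall, written separately in the test helpers) for distances on
graphs up to 40 nodes; exhaustive simple-path enumeration for σ counts,
stress, betweenness and edge betweenness on 100 random graphs of up to 7
nodes across all four directed/weighted mode combinations; a dense
full-spectrum eigensolver for eigenvector centrality up to 20 nodes; and
igraph as an external cross-check on a 20-node weighted graph. Closed
forms (star betweenness $(n-1)(n-2)/2$, star closeness $1/(n-1)$, complete
radiality 1, constancy on vertex-transitive graphs) are asserted exactly
for $n = 3..12$. These sizes keep the full suite under a minute while the
enumeration oracle remains tractable; the implementation itself handles
networks of thousands of nodes, with the $O(nm)$ Brandes pass as the
bottleneck.

## Known limitations

* Dijkstra's positivity requirement is enforced; zero or negative edge
  attributes are rejected rather than rerouted through a Johnson-style
  reweighting.
* Betweenness normalisation uses the connected-pair-free convention
  (divide by the total pair count); per-component normalisations are out
  of scope.
* The CLI's GraphML support covers nodes, edges, directedness, weights and
  double-typed node attributes — not nested graphs or ports.
* Eigenvector centrality on directed graphs reflects incoming-link
  structure only; on DAG-like graphs it may fail to converge (reported as
  an error) or concentrate on sinks.
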