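---
title: "Identifying critical edges with global-local hybrid centrality"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying critical edges with global-local hybrid centrality}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(critedge)
```

## The problem

In an undirected network — a protein-interaction map, a brain connectome, a
power grid — some edges matter far more than others for holding the system
together. A *critical edge* is one whose removal maximally accelerates the
fragmentation of the largest connected component. Identifying such edges
correctly matters both for protection (grid reliability, epidemic control)
and for targeted dismantling.

Classical edge indices use either purely **local** information (neighborhood
overlap around the edge) or purely **global** information (shortest-path
structure). Local indices are cheap and sharp inside clustered communities
but blind to bridges that close no triangles; global indices such as edge
betweenness see bridges but lack the fine-grained community signal. This
package implements a hybrid of the two families, the comparison baselines,
and the percolation framework used to judge them.

## The indices

For an edge $e_{ij}$ with endpoint degrees $k_i, k_j$:

* **DP** (degree product): $k_i k_j$.
* **EB** (edge betweenness): for every unordered node pair $\{s,t\}$ the
  fraction of $s$–$t$ geodesics through $e_{ij}$, summed and divided by
  $N(N-1)/2$, so $EB \in [0,1]$. Unreachable pairs contribute 0; $N$ stays
  the full node count on disconnected graphs.
* **BN** (bridgeness): $S_i S_j / S_e$ with $S$ the largest-clique sizes
  containing each endpoint / the whole edge (exact maximal-clique
  enumeration; exponential worst case, intended for desk-scale graphs).
* **DI** (diffusion intensity): mean count of *exclusive* neighbors — the
  neighbors of one endpoint (other endpoint excluded) not adjacent to the
  other endpoint.
* **FN** (first-order overlap): Jaccard similarity of
  $N_{i/j}$ and $N_{j/i}$, the neighbor sets with the opposite endpoint
  removed.
* **SN** (second-order overlap): Jaccard similarity of the two-step
  reachable sets $NN_{i/j}$ and $NN_{j/i}$.
* **EN** (enhanced neighborhood): $2\,SN + 3\,FN$.
* **EI** (motif-based importance): ratio of realized to maximal 3/4-node
  motif counts around the edge, scaled by the mean-geodesic-distance shift
  $|L - L'|$ caused by contracting it.
* **GLHC** (global-local hybrid centrality), the method of interest:
  $$GLHC(e_{ij}) = 3\,EB(e_{ij}) + 1\,SN(e_{ij}) + \tfrac{3}{2}\,FN(e_{ij}).$$

All indices share the convention *higher score = more important*, and all
weight constants are exposed as arguments with the defaults above.

## Conventions that the definitions leave open

Several of these indices are stated in the literature without pinning down
edge cases. The package fixes them as follows, and the choices are not
incidental — the first two are forced by the worked examples below.

**Two-step reachable sets.** $NN_{i/j}$ is the set of endpoints $w \ne i$ of
walks $i - u - w$ whose intermediate $u$ is not $j$. The far endpoint *may*
be $j$ itself or a first-order neighbor of $i$; only passing *through* $j$
is barred, and the origin is excluded. Among the natural variants (also
excluding $j$ as endpoint; distance-2 balls) this is the only one consistent
with the reference scores $SN(1,7) = SN(2,7) = 0.5$ on the clustered toy
network.

**Betweenness normalization.** The per-pair-fraction sum divided by
$N(N-1)/2$ is the only reading that reproduces the bridge value
$42/78 = 0.54$ on the triangle-free toy network; a ratio-of-sums reading
gives $48/88 = 0.55$ and is rejected.

**Empty unions.** FN and SN are defined as 0 when the Jaccard denominator is
empty (isolated edges, triangle-free surroundings).

**Score direction.** SN is sometimes described with a smaller-is-more-
important reading (low overlap suggests a bridge); the reference ranking
tables, and the positive SN weight inside EN and GLHC, use higher-is-more-
important. The package follows the tables consistently for every index.

**EI motif classes.** The published description of the motif metric reuses
the same symbols for realized and maximal counts, so a concrete reading must
be chosen: realized counts are exhaustive enumerations of triangles,
chordless 4-cycles through the edge, singly chorded 4-cycles split by
whether the edge is the chord ("inner") or a cycle edge ("outer"), and
4-cliques; maxima are the degree bounds $\min(k_i,k_j)-1$ for triangles and
$(k_i-1)(k_j-1)$ per quadrilateral class; $L, L'$ are mean geodesic
distances over connected pairs, with contraction merging the endpoints and
simplifying. EI is a comparison baseline only; it is cross-checked against
an independent brute-force implementation in the tests, and its weights and
reading are documented rather than canonical.

**Rounding.** Scores are computed and stored at full precision;
`round_half_up()` provides the two-decimal presentation used in the
reference tables (0.375 prints as 0.38). One reference cell, the clustered
network's GLHC entry for edge (2,7), prints as 1.10 although the exact value
$3\cdot 6/78 + 0.5 + 0.375 = 1.10577$ rounds to 1.11 under any standard
rule; and the entry for edge (1,13) prints as 0.59 although the graph
automorphism swapping nodes 4 and 13 forces it to equal the 0.60 printed for
(1,4). The package reports the arithmetically consistent values.

## Worked example

```{r toy}
g <- toy_clustered_network()
head(round_half_up(rank_edges(glhc(g))), 3)
```

The three top-ranked edges (1,2), (2,7), (1,7) are exactly the edges tying
the two hub communities together, with the true bridge (1,2) first — the
ordering that neither the purely local EN (which ranks (1,2) third) nor the
purely global EB (which ranks (1,7), (2,7) last) achieves on its own. On the
triangle-free variant every overlap index vanishes and the hybrid falls back
on its betweenness term:

```{r toy2}
h <- toy_triangle_free_network()
all(score_all_edges(h, "EN")$score == 0)
head(round_half_up(rank_edges(glhc(h))), 1)
```

## The percolation evaluation

A ranking is judged by removing edges worst-first and watching the largest
component collapse:

* **Robustness** $R = \frac{1}{E}\sum_{l=1}^{E} \xi_l$, where $\xi_l$ is the
  largest-component node fraction after the $l$-th removal. Lower $R$ means
  the ranking found the critical edges earlier.
* **Degradation curve**: the $(l/E, \xi_l)$ trajectory behind $R$.
* **Monotonicity** $M = \left[1 - \frac{\sum_i b_i(b_i-1)}{E(E-1)}\right]^2$
  over tie-group sizes $b_i$; 1 when every edge receives a distinct score.
  Grouping uses full-precision scores (tolerance $10^{-9}$) — rounding would
  manufacture ties.

The protocol ranks **once** and removes in that static order (an optional
`recompute = TRUE` mode re-ranks after every removal but is not part of the
standard evaluation). Ties are broken deterministically by canonical edge
key; a seeded random tie policy exists for sensitivity analysis, which
matters for tie-heavy rankings such as EN on triangle-free graphs. The curve
is computed by replaying removals backwards through a union-find structure,
so a full curve costs nearly linear time in $E$.

```{r percolation}
evaluate_method(h, "GLHC")
evaluate_method(h, "EN")
```

## Synthetic benchmark networks

Three seeded generators make the evaluation reproducible without external
data:

* `erdos_renyi(n, p)` — every pair independently an edge with probability
  $p$ (via igraph's G(n,p) sampler).
* `barabasi_albert(n, m)` — growth from $m$ isolated seed nodes; each
  arrival attaches $m$ edges to distinct nodes chosen proportionally to
  degree, the first arrival uniformly. This convention gives exactly
  $m(n-m)$ edges for every seed.
* `watts_strogatz(n, k, p)` — ring lattice ($k$ neighbors per node), each
  lattice edge rewired with probability $p$ to a uniform non-duplicate,
  non-self target, preserving $E = nk/2$.

`network_summary()` reports $N$, $E$, $\langle k\rangle = 2E/N$, the average
local clustering coefficient (degree-<2 nodes contributing 0; global
transitivity reported alongside) and degree assortativity (undefined, hence
`NA`, on regular graphs).

These generators emulate the degree mixing, clustering and growth mechanisms
of the standard model families, not any particular empirical system: no
community structure, no spatial embedding, no degree-degree correlations
beyond what the mechanisms induce. Passing tests on them demonstrates the
correctness and internal consistency of the indices and the evaluation
framework — not that any particular index will win on a given real network.

## Problem sizes and what the benchmark shows

The test suite exercises the full pipeline on the two 13-node worked
examples, on 200-node graphs from all three families (all nine indices,
including the clique- and motif-based ones), and on 500-node, mean-degree-6
graphs for the head-to-head robustness comparison averaged over five seeds.
These sizes keep the whole suite within a few minutes on a single core while
leaving every index in its exact (non-approximated) regime.

One empirical caveat emerged from that comparison and is worth stating
plainly: at this scale the hybrid index consistently beats its local
ingredient (mean $R(GLHC) < R(SN)$ in all three families) but **not** its
global ingredient. With $N = 500$ and $\langle k\rangle \approx 6$ the
normalized betweenness of a typical edge is of order $\bar d / E \approx
10^{-3}$, so the $3\,EB$ term is dominated by overlap terms of order
$10^{-1}$; and in sparse graphs the overlap-positive (triangle) edges that
local indices rank first are exactly the redundant ones. On the
Watts-Strogatz family the gap is large, because a $k=6$, $p=0.1$ lattice is
strongly clustered, so nearly every edge carries a large local signal while
the bridges carry the betweenness. The hybrid's advantage over pure
betweenness reported for networks one to two orders of magnitude larger
does not transfer unchanged to this desk scale; the corresponding
acceptance test records the fact rather than hiding it. Users applying the
method to small sparse networks may wish to raise `w_eb` (or rescale EB to
its observed range) — the weights are arguments, not constants.

## Known limitations

* Undirected, unweighted, static simple graphs only.
* BN enumerates maximal cliques exactly (exponential worst case) and EI
  contracts an edge and re-solves all-pairs distances per edge ($O(E\,NE)$
  overall); both are meant for networks up to a few thousand edges.
* GLHC itself is dominated by the $O(NE)$ betweenness pass; medium-scale
  networks (up to $\sim 10^5$ edges) are practical, web-scale graphs are not.
* The EI reading is one concrete interpretation of an ambiguous published
  definition and is excluded from any cross-implementation comparison.
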