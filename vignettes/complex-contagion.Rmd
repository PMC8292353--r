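---
title: "Measuring network connectedness and centrality for complex contagions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring network connectedness and centrality for complex contagions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(complexpaths)
```

## The model

A contagion spreads on an undirected, unweighted simple graph `G(V, E)` with
`n` nodes. Every node `i` carries an adoption threshold `T_i`, either
*absolute* (an integer count of activated neighbours, `T_i >= 1`) or
*fractional* (a fraction of the node's neighbours, `0 < T_i <= 1`).
Thresholds are *homogeneous* (one value for all nodes) or *heterogeneous*
(independent uniform draws from an interval — integers for absolute mode,
reals for fractional mode). Diffusion unfolds in discrete synchronous steps:
nodes active at step `t - 1` stay active, and any inactive node whose number
of active neighbours reaches its effective threshold becomes active at `t`.
The update is monotone, so the synchronous process, any asynchronous scan
order, and the minimal fixed point containing the seeds all coincide; the
test-suite verifies this equivalence against an asynchronous brute-force
oracle.

A *simple* contagion (`T = 1`) traverses any path of single ties; a
*complex* contagion (`T >= 2`) needs reinforcement, so it can only travel
where neighbourhoods are linked by enough mutually reinforcing ties. The
package's measures quantify exactly that.

### Fractional-to-integer conversion

The dynamics always operate on integer requirements. A fractional threshold
`T_i` on a node of degree `d_i` converts to `max(1, ceiling(T_i * d_i))`:
the smallest neighbour count that satisfies the stated fraction. An isolated
node has no neighbours to recruit it; its effective threshold degenerates to
1 (it only activates if seeded) and the conversion reports the degeneracy.

## Bridge width and locally sufficient bridges

For an ordered pair `(i, j)`, write `N[i]` for the closed neighbourhood of
`i` and `E(N[i])` for the edge set of the subgraph induced by `N[i]`
(including `i`'s own ties). The bridge from `N[i]` towards `j` is built from

* the overlap `O_ij = N[i] ∩ N[j]`,
* the disjoint set `D_ij = N[j] \ N[i]`, and
* the reinforcement set `R_ij`: members `x` of `D_ij` with
  `|E(N[i]) ∩ E(N[x])| >= 1`.

An edge lies in both `E(N[i])` and `E(N[x])` exactly when both endpoints lie
in `N[i] ∩ N[x]`, which is how both computation paths implement the test.
The bridge is `BW_ij = O_ij ∪ R_ij`, its width `W_ij = |BW_ij|`
(`= |O_ij| + |R_ij|`, the two parts being disjoint), and it is *sufficient*
when `W_ij >= T_j`. Under heterogeneous thresholds `R_ij` keeps only nodes
`x` that `N[i]` could itself activate, `|O_ix| >= T_x` — without this
filter a heterogeneous assignment could count reinforcement through nodes
that would never adopt.

`B_i` collects the partners `v != i` with `W_vi >= 1`; the local measure
`LB_i` is the fraction of partners `x ∈ B_i` whose *outgoing* bridge is
sufficient (`W_ix >= T_x`), and `LB` is the average of `LB_i` over nodes.
Two directional conventions meet here — partnerhood is defined through the
incoming width `W_vi`, sufficiency through the outgoing width `W_ix` — and
the package follows each formula literally rather than assuming `W` is
symmetric (it need not be: the reinforcement test is asymmetric in `i` and
`j`).

Design choices worth stating explicitly:

* **Formal vs loose reinforcement.** The reinforcement condition could be
  read more loosely as "`x` has at least one neighbour inside `N[i]`". The
  formal shared-induced-edge condition is the only unambiguous statement and
  is the default everywhere; the looser variant is available behind
  `prose_reinforcement = TRUE` for sensitivity checks. On a 4-node path the
  two demonstrably differ, which the tests pin down.
* **Empty partner sets.** `LB_i` for a node with `B_i = ∅` (e.g. an
  isolated node) is defined as 0 rather than left undefined, keeping the
  graph average total; the degenerate case is reported via a message.
* **Computation.** `bridge_report()` is a direct, readable set enumeration.
  `bridge_width_matrix()` computes all `n^2` widths at once with sparse
  matrix algebra: `|O|` as `Ncl %*% Ncl` for the closed-neighbourhood
  incidence `Ncl`, and the shared-edge counts assembled edge-by-edge from
  products of endpoint columns. The suite checks both paths against each
  other and against an independent brute-force oracle.

## Complex path length and complex centrality

The complex path from `i` to `j` is measured operationally: activate all of
`N[i]` at time 0, run the threshold dynamics to fixation, and let `CP_ij` be
the subgraph induced by the activated nodes. If `j` is not activated the
contagion cannot reach it and `PL_c_ij = 0`; otherwise `PL_c_ij` is the
number of vertices on a shortest `i -> j` path within `CP_ij`. Seeding the
entire closed neighbourhood is deliberate — the measure asks whether `i`'s
*neighbourhood* can export the contagion, mirroring the simulation protocol
that evaluates every node-plus-neighbourhood seed. Because every activated
non-seed node is recruited through active neighbours, `CP_ij` is connected
through `N[i]`, and a breadth-first search inside it suffices; equally short
geodesics are interchangeable since only the length is consumed downstream.

The node-level average divides the summed lengths over targets *outside*
`N[i]` by `n - |N[i]|`; when `N[i]` covers the whole graph the node has no
targets and `PL_c_i` is defined as 0. The graph-level `PL_c` averages
`PL_c_i` over all nodes. Two structural facts follow and are tested: at
`T = 1`, `PL_c_ij` equals the simple hop distance plus one (vertex count
instead of edge count); and any reachable target outside `N[i]` is at least
two hops away, so `PL_c_ij ∈ {0} ∪ {3, 4, ...}`.

Complex centrality is `CC_i = PL_c_i`: a node scores highly when its
neighbourhood can push the contagion far along chains of sufficient bridges.
A hub whose neighbourhood is internally edgeless scores 0 at `T = 2` — its
leaves can never reinforce each other — while a modest node inside a chain
of overlapping cliques scores highly. When the operative threshold is
unknown, `ensemble_complex_centrality()` averages `CC_i` over a range of
homogeneous absolute thresholds (default 2..6, chosen because `T = 1` makes
every strategy equivalent and spreading is minimal beyond 6).

Argmax ties (inevitable on vertex-transitive graphs) are broken
deterministically by smallest node label and reported via a message.

## Baseline centralities and seeding

Degree, betweenness, eigenvector and k-core centralities are delegated to
igraph. The percolation (collective-influence) score is
`(deg(i) - 1) * sum over nodes j at shortest-path distance exactly d of
(deg(j) - 1)` with `d = 3` by default; "reduced degree" is degree minus one,
and distance-`d` means exactly `d` in the shortest-path metric. Closeness is
the inverse mean distance to reachable nodes; reach counts nodes within a
configurable radius (default 2). Eigenvector centrality on a disconnected
graph is computed per connected component (each component's principal vector
scaled to maximum 1), since the global quantity is otherwise ill-defined;
this is reported via a message.

Seeding follows the clustered protocol: the focal node plus
`effective_threshold - 1` uniformly chosen neighbours; if the budget exceeds
the neighbourhood, nodes adjacent to the already-selected set are added one
at a time. Under fractional thresholds the same rule applies to the
effective (integer) threshold of the focal node — the natural extension of
the absolute-mode rule. A run counts as a *global cascade* when final
adoption reaches a configurable fraction of the population (default 0.5,
inclusive); the headline correlation analyses use mean adoption directly and
do not depend on this cutoff.

## Graph ensembles

**Rewired ring lattices.** Start from a ring of `n` nodes each tied to its
`k` nearest neighbours; visit every edge once in random order and, with
probability `p`, attempt a degree-preserving double-edge swap with a second,
uniformly chosen edge, rejecting swaps that would create self-loops or
multi-edges. This is the only randomisation consistent with keeping the
graph exactly k-regular at every `p`; rejection keeps it simple. Degree
preservation at all `p` is asserted in the tests. Connectivity is *not*
enforced — occasional disconnected realizations at high `p` are legitimate
members of the ensemble, and the experiment tables carry a `connected` flag
so analyses that need connectedness (e.g. the `T = 1` saturation check) can
condition on it.

**Clustering-tunable scale-free graphs.** Growth by preferential attachment
(`m` edges per arriving node, degree exponent near 3) with a triad-formation
step taken with probability `triad_p` after each preferential-attachment
edge, which raises clustering without changing the tail. The initial core is
an `m`-clique, so the edge count is exactly `m(n - m) + C(m, 2)`, the graph
is connected, and non-core degrees are at least `m`. Defaults `m = 4`,
`triad_p = 0.5` match the ensemble conditions of the validation experiments.

Both generators are bit-reproducible under `rng_seed`. Experiment runs
derive per-task seeds from a single master seed by a fixed affine counter
scheme (`derive_seed()`), so a table is byte-identical however its tasks are
ordered.

## What the synthetic experiments do and do not show

`run_plc_vs_adoption()` generates scale-free graphs, computes `PL_c` and the
mean adoption over *all* neighbourhood seedings from the same per-node
spreads, and correlates the two (Spearman, two-tailed; CI by bootstrap over
points, 10^4 resamples by default, since no analytic CI is assumed). At desk
scale (n = 300, 10 realizations per homogeneous fractional threshold in
{0.1, ..., 0.5}, 30 realizations for the heterogeneous condition
`T_i ~ U[0.1, 0.5]`) the correlation is about 0.96–0.98 pooled across
homogeneous conditions and about 0.99 across heterogeneous realizations.
The heterogeneous design needs the larger realization count because its
correlation is computed across realizations of a single condition, where the
between-point spread is much smaller.

`run_cascade_vs_lb()` reproduces the randomisation effect on lattices: at
`n = 200, k = 8`, both `LB` and the global-cascade frequency are maximal on
the pristine lattice and collapse at full rewiring for `T ∈ {2, 3, 4}`,
while `T = 1` saturates on connected realizations at any `p`.

These are synthetic validations. The generators emulate the degree
regularity, heavy tails and tunable clustering of the study ensembles, but
not degree–threshold correlations, homophily, community structure or edge
weights of real social networks; passing them shows the measures behave as
designed on the stated ensembles, not that any particular empirical network
will follow suit. The seeding tournament on empirical school or village
networks is supported by the same functions (`run_seeding_tournament()` with
any list of graphs read via `read_edge_list()`), but no empirical data ships
with the package.

## Numerical and test design choices

* Exact set algebra throughout the bridge computations — graphs of interest
  are at most a few thousand nodes, so no sampled approximation is used.
* The diffusion core is a sparse matrix-vector loop; a neighbourhood-seeded
  spread and its in-subgraph BFS share one adjacency structure.
* The brute-force oracle suite runs on every isomorphism class of connected
  graphs with 3–6 nodes (2 + 6 + 21 + 112 classes, enumerated by edge-subset
  masks and deduplicated by canonical form — the measures are
  label-invariant, so class representatives give full coverage at a fraction
  of the labeled-graph cost) plus 50 random graphs of up to 30 nodes,
  checking bridge sets, `LB`, and the synchronous-vs-asynchronous fixed
  point; monotonicity laws (in seeds, and against thresholds) are checked on
  200 randomized instances.
* Test and acceptance problem sizes (n = 200–300, 10–30 realizations) are
  the package's desk-scale defaults; the full-scale settings of the original
  ensembles (n = 1000, 50 realizations, 1000 trials per condition) are
  reachable through the same `experiment_config()` parameters.

## Known limitations

* `bridge_width_matrix()` materialises a dense `n x n` result; fine to a few
  thousand nodes, wasteful beyond.
* The Linear Threshold model redraws its private thresholds every run, and
  heterogeneous contagion thresholds are fixed per network realization (not
  redrawn per trial); both follow the canonical formulations, and the
  per-realization choice is exposed simply by reassigning thresholds.
* Directed, weighted and bipartite graphs are out of scope, as are
  continuous-time dynamics, SIR-type compartment models and threshold
  estimation from empirical adoption timing.
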