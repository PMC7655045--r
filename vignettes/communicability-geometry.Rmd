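---
title: "Communicability geometry, SI propagation, and two-group network comparison"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Communicability geometry, SI propagation, and two-group network comparison}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(commgeom)
```

# The model

## From SI dynamics to communicability

The package's geometric quantities are grounded in susceptible-infected
(SI) dynamics. On a binary undirected graph with adjacency `A`, the
probability `x_i(t)` that node `i` is infected evolves as

$$\dot x_i = \gamma\,(1 - x_i)\sum_j A_{ij} x_j .$$

Dropping the saturation factor gives the linearized system
$\dot x = \gamma A x$ with solution $x^\star(t) = e^{\gamma t A} x_0$ —
an upper bound on the exact solution, but useless for tracking an
epidemic because the semigroup $e^{tA}$ is unbounded. The surrogate used
throughout instead transforms $y_i = -\log(1 - x_i)$, under which the
exact system becomes $\dot y = \gamma A\,(1 - e^{-y})$. Bounding the
concave map $y \mapsto 1 - e^{-y}$ by its tangent line at the uniform
start $y(0) = -\log\alpha$ (where every node begins with the same
infection probability $\beta = c/n$ and $\alpha = 1-\beta$) linearizes
the system *in the transformed variable*, with closed-form solution

$$y(t) = \frac{\beta}{\alpha}\, e^{\alpha\gamma t A}\,\mathbf 1
  \;-\; \Big(\log\alpha + \frac{\beta}{\alpha}\Big)\,\mathbf 1 ,$$

and surrogate state $\tilde x = 1 - e^{-y}$, which starts exactly at
$\beta$, is nondecreasing, stays in $[0,1)$, and tightly upper-bounds the
exact solution (`integrate_exact_si()` vs `surrogate_si()` — the test
suite asserts the full chain exact ≤ surrogate ≤ linearized on random
graphs up to $n=100$). Because the derivation requires one common
tangent point, `surrogate_si()` rejects non-uniform starts rather than
silently extending the formula.

The surrogate depends on the graph only through $e^{\zeta A}\mathbf 1$
with $\zeta = \alpha\gamma t$. This is what motivates treating the
communicability matrix $G = e^{\zeta A}$ as the propagation structure of
the network: $G_{pp}$ (subgraph centrality, *circulability*) counts
closed walks at a node, $G_{pq}$ (*transmissibility*) counts walks
between two nodes, and

$$\xi_{pq} = \sqrt{G_{pp} + G_{qq} - 2G_{pq}}$$

is the Euclidean distance between the nodes' positions in the spectral
embedding $x_p = e^{\zeta\Lambda/2}U_{p\cdot}$. Every distance property
asserted in the tests (symmetry, identity of indiscernibles, triangle
inequality) follows from this embedding; the implementation exploits it
only through the guarantee that $\xi^2 \ge 0$ up to roundoff.

## Shortest communicability paths and normalization

`W = A ∘ X` weights each *existing* edge by its communicability
distance; shortest weighted paths on `W` (Dijkstra, all weights
positive) are the shortest communicability paths. As $\zeta \to 0$,
$G \to I$ and all distances approach $\sqrt 2$, so every communicability
path collapses onto a hop-count shortest path — the topological geometry
is the $\zeta \to 0$ limit of the communicability geometry, and the test
suite checks the collapse at $\zeta = 10^{-6}$.

Comparing raw path lengths across networks of different edge density
mostly measures density. The normalizer

$$\bar\xi = \frac{1}{m}\sum_{p,q} \xi_{pq} A_{pq}$$

is implemented as the literal ordered double sum divided by the
*undirected* edge count `m`: each undirected edge contributes twice, so
a graph whose edges all share distance `d` has $\bar\xi = 2d$. This
convention is deliberate — it is the one that reproduces the shipped
worked example (`mean_edge_comm_distance()` on `worked_example_graph()` gives
2.4797, and the normalized 1–6 path lengths 1.939/2.049) — and it
differs by a factor 2 from the per-edge mean, which callers averaging by
hand should keep in mind. `normalize_path_lengths()` is a plain
entrywise division, so the normalized matrix is invariant to any global
rescaling of `X`.

## Edge removal: circulability vs transmissibility

Removing an edge can only lengthen walks, so every entry of `G` is
entrywise nonincreasing under removal; both endpoint circulabilities and
all transmissibilities drop. The decomposition

$$\Delta\xi^2_{pq} = \Delta C_p + \Delta C_q - 2\Delta T_{pq}$$

(`delta_decomposition()`, verified to `1e-10` against the direct
difference of squared distance matrices) says *which* drop dominates.
Note that at the removed edge's own endpoints $\Delta\xi^2$ is always
negative — deleting the direct link costs more transmissibility between
its endpoints than circulability around them, without exception — so the
sign structure that distinguishes "path-lengthening" from
"path-shortening" removals lives in the network-wide summary, not at the
removed pair. `edge_removal_report()` therefore reports the mean
shortest-communicability-path-length change `delta_L_pct` as the primary
classifier (negative = lengths grew after removal, under the
original-minus-perturbed sign convention), alongside the endpoint
$\Delta\xi^2$ and the infection-time change. On the shipped 9-node
example, removals with `delta_L_pct < 0` slow full surrogate infection
by 20–37% while removals with `delta_L_pct > 0` cost only 2–4%: a
network can lose an edge and become *more* efficient at spreading.

The `delta_Gpp_pct`/`delta_Gpq_pct` columns average `G_pp` over nodes
and `G_pq` over edges "on shortest communicability paths". Which node
and edge multiset to average over is genuinely underdetermined; the
default takes the union over all pairs' shortest paths in the original
graph and evaluates both graphs on those fixed sets (making both
percentages provably nonnegative via monotonicity of `G`), with a
per-pair multiplicity variant available. These two columns are
descriptive summaries, not sharply defined statistics, and should be
read as such.

# The cohort pipeline

`build_group_mask()` binarizes every subject (strictly positive weight =
edge), computes the *reference group's* edge frequency matrix, keeps
edges with frequency strictly above `tau`, projects all subjects onto
the mask, and drops nodes isolated in the mask. The strict inequality
fixes the boundary: an edge present in exactly half the reference
subjects survives `tau = 0.4` but not `tau = 0.5`. `tau` is capped at
0.9 — a threshold of 1 would demand unanimity and empty most masks.

`permutation_test()` compares group means per node pair, with a null
distribution built by reassigning subjects to groups of the original
sizes. The two-sided p-value uses the add-one estimator
$p = (1 + \#\{|\Delta_{rand}| \ge |\Delta_{obs}|\})/(1 + B)$, which is
never zero and makes the resolution bound explicit: with $B$
permutations no p-value can fall below $1/(B+1)$, so Bonferroni
significance across $\kappa$ pairs is only reachable when
$1/(B+1) < \alpha/\kappa$. Pairs with an infinite length in any subject
(cross-component) are excluded and counted rather than imputed.
Correction is Benjamini-Hochberg by default ("FDR" without
qualification is read as BH; Benjamini-Yekutieli is available), using
the step-up rule's non-strict boundary, while Bonferroni uses the strict
$p < \alpha/\kappa$; at equal $\alpha$ the Bonferroni set is always
nested in the BH set.

Defaults: $\zeta = 1$ everywhere (the geometry degenerates to hop
counts near 0 and overweights long walks well above 1; 1 is the
conventional midpoint and all shipped anchors use it), `n_perm = 1000`,
$\alpha = 0.05$, measure = subject-wise normalized shortest
communicability path length (each subject divided by its *own*
$\bar\xi$).

# The synthetic generator

`generate_cohort()` emulates the *structure* of a two-group connectome
study: a common base graph (default: connected Erdős–Rényi, $n = 60$
nodes, edge probability 0.15 — mean degree ≈ 9, in the range of
mask-thresholded structural connectomes), 20 subjects per group, a
planted difference of 12 base edges removed in the disease-like group
(chosen so the base stays connected, mirroring the edge-removal framing
of the perturbation analysis), and independent per-pair flip noise of
0.02 per subject. Matrices are emitted as weights so the binarization
stage is exercised; the planted pair list is returned for recovery
scoring (`planted_recall()`).

What the generator does *not* emulate: weighted streamline counts and
their heavy-tailed distributions, spatially correlated tractography
error (flips are independent across pairs), hemispheric topology (node
tags are assigned by index blocks, not geometry), and subject-level
covariates. Passing recovery tests therefore demonstrates that the
pipeline detects localized connectivity differences against independent
edge noise at realistic density — not that it would survive the
correlated, confounded noise of real imaging data.

At the default condition the pipeline recovers all 12 planted pairs at
`tau = 0.3` under BH (recall 1.0), a null cohort (no planted edges) has
raw $p < 0.05$ fraction 0.0497 ∈ [0.03, 0.07], and at every
`tau ∈ {0, 0.1, …, 0.9}` the communicability measure flags at least as
many true pairs as the hop-count measure — the desk-scale analogue of
communicability's sensitivity advantage. These numbers are computed, not
quoted: the acceptance test file runs exactly these experiments.

# Numerical choices

* **Matrix exponential** by symmetric eigendecomposition
  ($A = U\Lambda U^T$, $G = U e^{\zeta\Lambda} U^T$), not
  scaling-and-squaring: symmetry is enforced exactly by construction
  ($G \leftarrow (G + G^T)/2$ against roundoff) and the decomposition is
  reused across $\zeta$ and by the spectral SI solutions. Dense
  matrices throughout: at the package's design scale ($n$ up to a few
  hundred) sparsity machinery buys nothing.
* **Negative squared distances**: $\xi^2$ entries in $[-10^{-9}, 0)$ are
  clipped to zero (roundoff on near-coincident embeddings); anything
  below $-10^{-9}$ raises, because a genuinely negative Gram-type
  residual means `G` is broken, and clipping it would hide the bug.
* **Shortest paths**: igraph's Dijkstra (label-setting, positive
  weights). Predecessor tables store one optimal path per pair;
  reported paths are deterministic for a fixed input. Disconnected
  pairs carry `Inf`, never a sentinel value.
* **Exact SI**: `deSolve::ode` (lsoda), `rtol 1e-8`, `atol 1e-10`,
  states clipped to $[0,1]$ within tolerance.
* **Infection time**: the surrogate's minimum-over-nodes $y_i(t)$ is
  monotone in $t$, so the crossing of $-\log(1-\theta)$ is found by
  doubling bracket plus `uniroot` to `1e-10`. The crossing level
  $\theta$ defaults to 0.99: "all nodes infected" has no canonical
  cutoff for a probability model, and percentage *changes* of
  `infection_time()` under perturbation — the quantity the edge-removal
  report uses — are insensitive to $\theta$, which stays exposed as an
  argument.
* **Permutations**: label reassignments are drawn without replacement
  preserving group sizes; the null contrast for all pairs is one matrix
  product per run. The seed is mandatory, and the caller's RNG state is
  saved and restored around every seeded generator.

# Test design and problem sizes

Oracles are independent of the code paths they check: the
communicability matrix is validated against truncated power-series
summation, path lengths against exhaustive enumeration over simple
paths (graphs of 4–8 nodes, where enumeration is exact and fast), the
complete-graph SI solution against the scalar logistic closed form, and
the BH/Bonferroni flags against a hand-applied step-up rule. Property
loops use 20–50 seeded random graphs of 4–15 nodes; the SI bound chain
additionally runs one Erdős–Rényi graph with $n = 100$, $p = 0.1$.
Cohort experiments run at the generator's default condition (60 nodes,
20+20 subjects), with 1000 permutations for the headline runs and 200
inside the ten-threshold sweep. The full suite completes in under two
minutes on one core.

# Known limitations

* Undirected, binary, loop-free graphs only: no directed or signed
  variants, no weighted (non-binarized) analysis, and no
  normalized-Laplacian communicability.
* $\zeta$ is a free parameter with default 1; the package exposes it
  everywhere but ships no data-driven selection rule.
* The `delta_Gpp_pct`/`delta_Gpq_pct` averaging sets are conventions
  (see above), and endpoint $\Delta\xi^2$ alone does not classify
  removals.
* The permutation test treats node pairs marginally; it controls error
  rates per pair (BH/Bonferroni across pairs) but models no dependence
  between pairs, which on real connectomes is substantial.
* `infection_time()` is defined on the surrogate dynamics, not the
  exact ODE; it inherits the surrogate's upper-bound bias (earlier
  crossings than the exact solution would give).
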