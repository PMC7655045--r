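# commgeom

Communicability-distance geometry on binary undirected networks, with a
two-group connectome comparison pipeline built on top of it.

## The problem

In network neuroscience — and in any setting where a diffusing factor
(a disease agent, information, a signal) spreads over a graph — the
hop-count shortest path is often a poor proxy for how the network is
actually traversed. Communicability theory replaces hop counts with a
walk-weighted geometry. For a binary symmetric adjacency matrix `A` and a
parameter `ζ > 0`, the communicability matrix is

    G = exp(ζA),   G_pq = Σ_k ζ^k (A^k)_pq / k!

`G_pp` (the subgraph centrality) measures how strongly a diffusing factor
*circulates* around node `p`; `G_pq` measures its *transmissibility*
between `p` and `q`. Their combination

    ξ_pq = sqrt(G_pp + G_qq − 2 G_pq)

is a Euclidean distance between nodes (the spectral embedding
`x_p = e^(ζΛ/2) U[p,]` realizes it), large when two nodes trap the factor
in separate "islands" and small when they exchange it freely. Weighting
each edge of the graph by `ξ` and running Dijkstra on `W = A ∘ X` gives
**shortest communicability paths**; dividing by the network's
edge-averaged distance

    ξ̄ = Σ_{p,q} ξ_pq A_pq / m

makes path lengths comparable across networks of different density
(`Ŝ = S / ξ̄`). These quantities connect to epidemic dynamics: the
susceptible-infected (SI) model's bounded surrogate solution is an
explicit function of `e^(ζA)·1`, so communicability is not a heuristic
but the closed-form skeleton of SI propagation on the graph.

The package implements this whole chain:

* `communicability()`, `communicability_matrix()`,
  `communicability_distance()`, `communicability_weights()` — the
  matrix-function layer (symmetric eigendecomposition throughout);
* `shortest_communicability_paths()`, `shortest_topological_paths()`,
  `mean_edge_comm_distance()`, `normalize_path_lengths()`,
  `fixed_path_length()` — path geometry and normalization;
* `integrate_exact_si()`, `linearized_si()`, `surrogate_si()`,
  `infection_time()` — SI dynamics: exact ODE integration, the unbounded
  linearized solution, and the bounded log-transform surrogate;
* `is_cyclic_edge()`, `delta_decomposition()`, `edge_removal_report()` —
  edge-removal diagnostics separating circulability from transmissibility
  (`Δξ²_pq = ΔC_p + ΔC_q − 2ΔT_pq`);
* `cohort()`, `build_group_mask()`, `permutation_test()`,
  `adjust_pvalues()`, `classify_significant_pairs()`,
  `node_median_profile()`, `tau_sweep()` — two-group comparison:
  binarization, reference-group mask thresholding, label-permutation
  tests with Benjamini-Hochberg and Bonferroni correction;
* `worked_example_graph()`, `random_graph()`, `cohort_spec()`, `generate_cohort()` —
  the worked-example fixture and a synthetic cohort generator with
  planted, recoverable group differences.

A command-line surface (`commgeom_cli()`, installed script
`inst/cli/commgeom`) exposes the pipeline as subcommands
(`distance`, `paths`, `si-run`, `perturb`, `simulate-cohort`,
`cohort-run`, `tau-sweep`).

## Worked example

The package ships a 9-node bridgeless example graph in which the
topological and communicability geometries disagree:

```r
library(commgeom)
net <- worked_example_graph()
cs  <- communicability(net, zeta = 1)

xi_bar <- mean_edge_comm_distance(cs, net)
xi_bar
#> [1] 2.479726

pl <- shortest_communicability_paths(cs)
extract_path(shortest_topological_paths(net), "1", "6")
#> [1] "1" "2" "4" "6"
extract_path(pl, "1", "6")
#> [1] "1" "9" "8" "7" "6"

s_hat <- normalize_path_lengths(pl, xi_bar)$s_hat
s_hat["1", "6"]
#> [1] 1.938627
fixed_path_length(cs, c("1", "2", "4", "6")) / xi_bar
#> [1] 2.048719
```

The 3-hop route 1–2–4–6 runs through a dense cluster whose edges carry
large communicability distances; the 4-hop peripheral route 1–9–8–7–6 is
*shorter* in this geometry (1.94 vs 2.05 normalized units). Removing
edges shows the two failure modes of connectivity loss:

```r
p <- si_parameters(gamma = 0.005, beta = 1/9, n = 9)
edge_removal_report(net, list(c(1, 2), c(8, 9), c(2, 4)), p = p)
#>    edge delta_L_pct delta_Gpp_pct delta_Gpq_pct delta_tinf_pct delta_xi2
#> 1 {1,2}  -25.448028      6.823741     10.409224      37.308058 -3.196114
#> 2 {8,9}  -21.491154      4.133896      4.594629      20.075925 -1.803514
#> 3 {2,4}    1.422930     21.680908     31.741141       4.290012 -1.802644
```

Removing `{1,2}` or `{8,9}` lengthens the mean shortest communicability
path by >20% (`delta_L_pct < 0`: original minus perturbed over original)
and slows full infection by 20–37%; removing `{2,4}` *shortens* the mean
path — the residual network trades circulability for transmissibility —
and barely slows the spread (+4.3%).

On synthetic cohorts the permutation pipeline recovers planted edge
removals (12 planted edges, 20+20 subjects, 2% flip noise) with recall
1.0 at `tau = 0.3` under BH correction, while staying calibrated
(null-cohort raw `p < 0.05` fraction 0.0497) — see the test suite and
the vignette for the exact runs.

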