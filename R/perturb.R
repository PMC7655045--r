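#' Is an edge cyclic?
#'
#' A cyclic edge is one whose removal leaves the number of connected
#' components unchanged (it lies on a cycle); the alternative is a bridge.
#'
#' @param net a [comm_network()].
#' @param edge length-2 vector of node indices or labels; must be an edge.
#' @return `TRUE` for a cyclic edge, `FALSE` for a bridge.
#' @export
is_cyclic_edge <- function(net, edge) {
  ij <- resolve_edge(net, edge)
  before <- igraph::components(as_igraph(net))$no
  after <- igraph::components(as_igraph(drop_edge(net, ij)))$no
  after == before
}

#' Circulability/transmissibility decomposition of an edge removal
#'
#' For the removal of edge `e` and a node pair `(p, q)`, the change of the
#' squared communicability distance splits exactly into changes of the two
#' endpoint circulabilities (diagonal communicabilities) and the
#' transmissibility between them:
#' \deqn{\Delta\xi^2_{pq} = \Delta C_p + \Delta C_q - 2\,\Delta T_{pq},}
#' with every Delta meaning original minus perturbed. Since removing an
#' edge can only lengthen walks, all `Delta C` and `Delta T` are
#' nonnegative; the *sign* of `Delta xi^2` says whether the removal cost
#' more transmissibility (negative) or more circulability (positive).
#'
#' @param net a [comm_network()].
#' @param edge the edge to remove (indices or labels).
#' @param zeta communicability parameter, default 1.
#' @return A list with matrices `delta_C` (n x n, `Delta C_p + Delta C_q`
#'   split per pair via its two addends `dC` vector), `delta_T` and
#'   `delta_xi2`, plus `dC` (per-node circulability drop). The identity
#'   above holds entrywise to roundoff.
#' @export
delta_decomposition <- function(net, edge, zeta = 1) {
  ij <- resolve_edge(net, edge)
  G0 <- communicability_matrix(net, zeta)$G
  G1 <- communicability_matrix(drop_edge(net, ij), zeta)$G
  dG <- G0 - G1
  dC <- diag(dG)
  delta_T <- dG
  diag(delta_T) <- 0
  delta_xi2 <- outer(dC, dC, `+`) - 2 * dG
  diag(delta_xi2) <- 0
  list(edge = ij, dC = dC, delta_T = delta_T, delta_xi2 = delta_xi2)
}

#' Edge-removal report
#'
#' For each requested cyclic edge, quantifies the structural and dynamical
#' effect of its removal. All percentages follow the convention
#' `100 * (original - perturbed) / original`, except the infection time
#' where `100 * (perturbed - original) / original` reports how much
#' *longer* full infection takes after removal. Reported columns:
#'
#' * `delta_L_pct`: percent change of the mean finite shortest
#'   communicability path length;
#' * `delta_Gpp_pct`: percent change of the mean subgraph centrality
#'   (circulability) over the nodes lying on shortest communicability paths
#'   of the original graph;
#' * `delta_Gpq_pct`: percent change of the mean communicability
#'   (transmissibility) over the edges lying on those paths;
#' * `delta_tinf_pct`: percent change of the surrogate full-infection time;
#' * `delta_xi2`: change of the squared communicability distance at the
#'   removed edge's own endpoints.
#'
#' The averaging sets for `delta_Gpp_pct`/`delta_Gpq_pct` default to the
#' union of nodes (resp. edges) over all pairs' shortest communicability
#' paths in the *original* graph, with both graphs' communicabilities
#' averaged over those fixed sets (so entrywise monotonicity of `G` under
#' removal makes both percentages nonnegative); `averaging = "per_pair"`
#' instead averages over every path node/edge of every pair with
#' multiplicity, using each graph's own shortest paths. Neither convention
#' is canonical; both are approximate summaries of where shortest
#' communicability paths spend their communicability.
#'
#' Bridges are skipped with a warning: their removal changes the
#' connectivity regime, so the percentages are not comparable.
#'
#' @param net a [comm_network()].
#' @param edges list of length-2 vectors (indices or labels), or `NULL` for
#'   all cyclic edges.
#' @param zeta communicability parameter.
#' @param p an [si_parameters()] for the infection-time column, or `NULL`
#'   to skip it.
#' @param theta crossing threshold passed to [infection_time()].
#' @param averaging `"union"` (default) or `"per_pair"`, see Details.
#' @return A data frame with one row per analyzed edge.
#' @examples
#' net <- worked_example_graph()
#' edge_removal_report(net, list(c(1, 2), c(2, 4)),
#'                     p = si_parameters(0.005, beta = 1/9, n = 9))
#' @export
edge_removal_report <- function(net, edges = NULL, zeta = 1, p = NULL,
                                theta = 0.99, averaging = c("union", "per_pair")) {
  averaging <- match.arg(averaging)
  if (is.null(edges)) {
    el <- edge_list(net)
    edges <- lapply(seq_len(nrow(el)), function(k) el[k, ])
    edges <- Filter(function(e) is_cyclic_edge(net, e), edges)
  }
  cs0 <- communicability(net, zeta)
  pl0 <- shortest_communicability_paths(cs0)
  L0 <- as.numeric(mean_path_length(pl0))
  sets0 <- path_sets(pl0)
  avg0 <- path_set_averages(cs0$G, sets0, averaging)
  t0 <- if (!is.null(p)) infection_time(net, p, theta) else NA_real_

  rows <- lapply(edges, function(e) {
    ij <- resolve_edge(net, e)
    lab <- paste0("{", net$labels[ij[1L]], ",", net$labels[ij[2L]], "}")
    if (!is_cyclic_edge(net, ij)) {
      warning("edge ", lab, " is a bridge; skipped")
      return(NULL)
    }
    net1 <- drop_edge(net, ij)
    cs1 <- communicability(net1, zeta)
    pl1 <- shortest_communicability_paths(cs1)
    L1 <- as.numeric(mean_path_length(pl1))
    sets1 <- if (averaging == "union") sets0 else path_sets(pl1)
    avg1 <- path_set_averages(cs1$G, sets1, averaging)
    dxi2 <- (cs0$X[ij[1L], ij[2L]]^2) - (cs1$X[ij[1L], ij[2L]]^2)
    t1 <- if (!is.null(p)) infection_time(net1, p, theta) else NA_real_
    data.frame(
      edge = lab,
      delta_L_pct = 100 * (L0 - L1) / L0,
      delta_Gpp_pct = 100 * (avg0["Gpp"] - avg1["Gpp"]) / avg0["Gpp"],
      delta_Gpq_pct = 100 * (avg0["Gpq"] - avg1["Gpq"]) / avg0["Gpq"],
      delta_tinf_pct = if (is.null(p)) NA_real_ else 100 * (t1 - t0) / t0,
      delta_xi2 = dxi2,
      row.names = NULL
    )
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(edge = character(), delta_L_pct = numeric(),
                      delta_Gpp_pct = numeric(), delta_Gpq_pct = numeric(),
                      delta_tinf_pct = numeric(), delta_xi2 = numeric())
  }
  out
}

# node visit counts and edge incidences over all pairs' shortest
# communicability paths of one graph
path_sets <- function(pl) {
  n <- nrow(pl$lengths)
  node_hits <- numeric(n)
  edge_from <- integer(0)
  edge_to <- integer(0)
  for (i in seq_len(n - 1L)) {
    for (j in seq((i + 1L), n)) {
      if (!is.finite(pl$lengths[i, j])) next
      path <- j
      while (path[1L] != i) path <- c(pl$predecessors[i, path[1L]], path)
      node_hits[path] <- node_hits[path] + 1L
      edge_from <- c(edge_from, path[-length(path)])
      edge_to <- c(edge_to, path[-1L])
    }
  }
  list(node_hits = node_hits, edge_from = edge_from, edge_to = edge_to)
}

# mean G_pp over path nodes and mean G_pq over path edges
path_set_averages <- function(G, sets, averaging) {
  if (averaging == "union") {
    nodes <- which(sets$node_hits > 0)
    ekey <- unique(paste(pmin(sets$edge_from, sets$edge_to),
                         pmax(sets$edge_from, sets$edge_to)))
    eidx <- do.call(rbind, lapply(strsplit(ekey, " "), as.integer))
    c(Gpp = mean(diag(G)[nodes]), Gpq = mean(G[eidx]))
  } else {
    c(Gpp = sum(diag(G) * sets$node_hits) / sum(sets$node_hits),
      Gpq = mean(G[cbind(sets$edge_from, sets$edge_to)]))
  }
}
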