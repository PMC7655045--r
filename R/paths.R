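#' Shortest communicability path lengths
#'
#' Shortest weighted paths on the communicability-weighted adjacency `W`:
#' the length of the shortest communicability path between two nodes is the
#' minimum, over all paths joining them, of the summed communicability
#' distances of the path's edges. Computed with Dijkstra's label-setting
#' algorithm (all weights are positive). Pairs in different components get
#' `Inf`, never a sentinel value.
#'
#' @param cs a `comm_set` with `W` populated (see [communicability()]).
#' @return A `path_lengths` object: `lengths` (n x n, symmetric, zero
#'   diagonal), `predecessors` (n x n integer; `predecessors[i, j]` is the
#'   node before `j` on a shortest path from `i`, `NA` on the diagonal and
#'   across components), and `kind = "communicability"`.
#' @examples
#' pl <- shortest_communicability_paths(communicability(worked_example_graph()))
#' extract_path(pl, "1", "6")   # 1-9-8-7-6, not the 3-hop topological path
#' @export
shortest_communicability_paths <- function(cs) {
  stopifnot(inherits(cs, "comm_set"))
  if (is.null(cs$W)) stop("W not populated; call communicability() or communicability_weights()")
  g <- igraph::graph_from_adjacency_matrix(cs$W, mode = "undirected", weighted = TRUE)
  path_length_matrix(g, weighted = TRUE, labels = cs$labels, kind = "communicability")
}

#' Shortest topological path lengths
#'
#' Hop-count (breadth-first) shortest paths on the unweighted graph; the
#' `zeta -> 0` limit of the communicability paths.
#'
#' @param net a [comm_network()].
#' @return A `path_lengths` object with integer-valued finite entries and
#'   `kind = "topological"`.
#' @export
shortest_topological_paths <- function(net) {
  stopifnot(inherits(net, "comm_network"))
  g <- as_igraph(net)
  path_length_matrix(g, weighted = FALSE, labels = net$labels, kind = "topological")
}

path_length_matrix <- function(g, weighted, labels, kind) {
  n <- igraph::vcount(g)
  w <- if (weighted) igraph::E(g)$weight else NA
  lengths <- igraph::distances(g, weights = w, algorithm = if (weighted) "dijkstra" else "unweighted")
  pred <- matrix(NA_integer_, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n)) {
    # unreachable targets are expected on disconnected graphs; igraph's
    # warning about them is noise here
    sp <- suppressWarnings(
      igraph::shortest_paths(g, from = i, to = igraph::V(g),
                             weights = w, predecessors = TRUE))
    p <- as.integer(sp$predecessors)
    p[i] <- NA_integer_
    p[!is.finite(lengths[i, ])] <- NA_integer_
    pred[i, ] <- p
  }
  dimnames(lengths) <- list(labels, labels)
  structure(list(lengths = lengths, predecessors = pred, kind = kind),
            class = "path_lengths")
}

#' @export
print.path_lengths <- function(x, ...) {
  cat("<path_lengths> kind = ", x$kind, ", n = ", nrow(x$lengths),
      ", infinite pairs = ", sum(!is.finite(x$lengths[upper.tri(x$lengths)])),
      "\n", sep = "")
  invisible(x)
}

#' Reconstruct one shortest path
#'
#' Walks the predecessor table of a [shortest_communicability_paths()] /
#' [shortest_topological_paths()] result back from `to` to `from`.
#'
#' @param pl a `path_lengths` object.
#' @param from,to node labels or indices.
#' @return Character vector of node labels along one optimal path, or `NULL`
#'   if the pair is disconnected.
#' @export
extract_path <- function(pl, from, to) {
  labels <- rownames(pl$lengths)
  i <- if (is.character(from)) match(from, labels) else as.integer(from)
  j <- if (is.character(to)) match(to, labels) else as.integer(to)
  if (is.na(i) || is.na(j)) stop("unknown node")
  if (!is.finite(pl$lengths[i, j])) return(NULL)
  path <- j
  while (path[1L] != i) {
    p <- pl$predecessors[i, path[1L]]
    if (is.na(p)) return(NULL)
    path <- c(p, path)
  }
  labels[path]
}

#' Edge-averaged communicability distance
#'
#' The per-network normalizer `xi_bar`: the ordered double sum
#' `sum_{p,q} X[p, q] * A[p, q]` — each undirected edge counted twice —
#' divided by the undirected edge count `m`. Note this convention (taken
#' literally from the defining sum) is twice the mean distance per
#' undirected edge: a graph whose edges all have distance `d` returns `2 d`.
#'
#' @param cs a `comm_set` with `X` populated.
#' @param net the corresponding [comm_network()]; must have at least one edge.
#' @return Positive scalar `xi_bar`.
#' @examples
#' mean_edge_comm_distance(communicability(worked_example_graph()), worked_example_graph())  # ~2.4797
#' @export
mean_edge_comm_distance <- function(cs, net) {
  stopifnot(inherits(cs, "comm_set"), inherits(net, "comm_network"))
  if (is.null(cs$X)) stop("X not populated")
  m <- n_edges(net)
  if (m < 1L) stop("xi_bar is undefined for an edgeless graph")
  sum(cs$X * net$adjacency) / m
}

#' Normalize path lengths by the edge-average distance
#'
#' Divides every entry of a path-length matrix by the network's `xi_bar`,
#' yielding the unitless normalized shortest communicability path length
#' matrix that makes subjects of different edge density comparable.
#'
#' @param pl a `path_lengths` object.
#' @param xi_bar positive scalar from [mean_edge_comm_distance()].
#' @return A `normalized_paths` object with fields `xi_bar` and `s_hat`
#'   (`Inf` entries preserved).
#' @export
normalize_path_lengths <- function(pl, xi_bar) {
  stopifnot(inherits(pl, "path_lengths"))
  if (!is.numeric(xi_bar) || length(xi_bar) != 1L || !is.finite(xi_bar) || xi_bar <= 0) {
    stop("xi_bar must be a single positive number")
  }
  structure(list(xi_bar = xi_bar, s_hat = pl$lengths / xi_bar, kind = pl$kind),
            class = "normalized_paths")
}

#' Communicability length of a fixed node sequence
#'
#' Sums the `W` weights along an explicitly given path; used to compare a
#' candidate route (for example the topological shortest path) against the
#' optimal communicability path.
#'
#' @param cs a `comm_set` with `W` populated.
#' @param nodes vector of node labels or indices; consecutive entries must
#'   be edges of the network.
#' @return Scalar sum of communicability distances along the path.
#' @examples
#' cs <- communicability(worked_example_graph())
#' fixed_path_length(cs, c("1", "2", "4", "6")) / 2.4797  # ~2.049 on fig 5
#' @export
fixed_path_length <- function(cs, nodes) {
  stopifnot(inherits(cs, "comm_set"))
  if (is.null(cs$W)) stop("W not populated")
  labels <- cs$labels
  idx <- if (is.character(nodes)) match(nodes, labels) else as.integer(nodes)
  if (anyNA(idx)) stop("unknown node in path")
  if (length(idx) < 2L) stop("a path needs at least two nodes")
  total <- 0
  for (k in seq_len(length(idx) - 1L)) {
    w <- cs$W[idx[k], idx[k + 1L]]
    if (w <= 0) {
      stop("nodes ", labels[idx[k]], " and ", labels[idx[k + 1L]],
           " are not adjacent: not a path in this network")
    }
    total <- total + w
  }
  total
}

#' Mean finite shortest path length
#'
#' Mean of the finite entries of a path-length matrix over unordered
#' distinct pairs; infinite (cross-component) pairs are excluded and their
#' count attached as an attribute.
#'
#' @param pl a `path_lengths` object.
#' @return Scalar mean, with attribute `n_infinite`.
#' @export
mean_path_length <- function(pl) {
  stopifnot(inherits(pl, "path_lengths"))
  v <- pl$lengths[upper.tri(pl$lengths)]
  fin <- is.finite(v)
  out <- mean(v[fin])
  attr(out, "n_infinite") <- sum(!fin)
  out
}
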