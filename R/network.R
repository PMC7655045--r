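#' Construct a binary undirected network
#'
#' The universal input object of the package: an ordered set of node labels
#' together with a binary, symmetric adjacency matrix with zero diagonal
#' (simple undirected graph, no self-loops).
#'
#' @param adjacency square numeric matrix with entries in \{0, 1\}, symmetric,
#'   zero diagonal.
#' @param labels character vector of unique node labels, one per node.
#'   Defaults to the adjacency dimnames, or `"v1" ... "vn"`.
#' @return An object of class `comm_network` with elements `labels`
#'   (character) and `adjacency` (integer matrix).
#' @examples
#' net <- comm_network(rbind(c(0, 1, 0), c(1, 0, 1), c(0, 1, 0)))
#' n_nodes(net)
#' n_edges(net)
#' @export
comm_network <- function(adjacency, labels = NULL) {
  adjacency <- as.matrix(adjacency)
  if (nrow(adjacency) != ncol(adjacency)) {
    stop("adjacency must be square, got ", nrow(adjacency), " x ", ncol(adjacency))
  }
  n <- nrow(adjacency)
  if (n < 1L) stop("network must have at least one node")
  if (anyNA(adjacency)) stop("adjacency contains missing values")
  if (!all(adjacency %in% c(0, 1))) {
    stop("adjacency must be binary (entries 0 or 1); use binarize_subject() for weighted input")
  }
  if (!isTRUE(all.equal(adjacency, t(adjacency), check.attributes = FALSE))) {
    stop("adjacency must be symmetric")
  }
  if (any(diag(adjacency) != 0)) stop("adjacency must have zero diagonal (no self-loops)")
  if (is.null(labels)) {
    labels <- rownames(adjacency)
    if (is.null(labels)) labels <- paste0("v", seq_len(n))
  }
  labels <- as.character(labels)
  if (length(labels) != n) stop("need exactly ", n, " labels, got ", length(labels))
  if (anyDuplicated(labels)) stop("node labels must be unique")
  adjacency <- matrix(as.integer(adjacency), n, n, dimnames = list(labels, labels))
  structure(list(labels = labels, adjacency = adjacency), class = "comm_network")
}

#' Build a network from an edge list
#'
#' @param edges two-column matrix or data frame of node pairs. Columns may be
#'   integer indices or character labels.
#' @param n_nodes total node count (indices up to `n_nodes` allowed even if
#'   isolated). Ignored when `edges` is character.
#' @param labels optional node labels.
#' @param one_based logical; are integer indices 1-based (default) or 0-based?
#' @return A [comm_network()] object.
#' @examples
#' network_from_edges(cbind(c(1, 2), c(2, 3)), n_nodes = 3)
#' @export
network_from_edges <- function(edges, n_nodes = NULL, labels = NULL, one_based = TRUE) {
  edges <- as.matrix(edges)
  if (ncol(edges) < 2L) stop("edge list needs at least two columns")
  u <- edges[, 1L]
  v <- edges[, 2L]
  if (is.character(u)) {
    if (is.null(labels)) labels <- sort(unique(c(u, v)))
    iu <- match(u, labels)
    iv <- match(v, labels)
    if (anyNA(iu) || anyNA(iv)) stop("edge list mentions labels not in `labels`")
  } else {
    iu <- as.integer(u)
    iv <- as.integer(v)
    if (!one_based) {
      iu <- iu + 1L
      iv <- iv + 1L
    }
    if (is.null(n_nodes)) n_nodes <- max(iu, iv, 1L)
    if (any(iu < 1L | iv < 1L | iu > n_nodes | iv > n_nodes)) {
      stop("edge indices out of range 1..", n_nodes)
    }
  }
  n <- if (is.null(n_nodes)) length(labels) else n_nodes
  if (any(iu == iv)) stop("self-loops are not allowed")
  A <- matrix(0L, n, n)
  A[cbind(iu, iv)] <- 1L
  A[cbind(iv, iu)] <- 1L
  comm_network(A, labels = labels)
}

#' @export
print.comm_network <- function(x, ...) {
  cat("<comm_network> ", n_nodes(x), " nodes, ", n_edges(x), " edges\n", sep = "")
  invisible(x)
}

#' Node and edge counts
#'
#' @param net a [comm_network()].
#' @return Integer count.
#' @export
n_nodes <- function(net) length(net$labels)

#' @rdname n_nodes
#' @export
n_edges <- function(net) sum(net$adjacency) %/% 2L

#' Edge list of a network
#'
#' @param net a [comm_network()].
#' @return Two-column integer matrix of node indices, one row per undirected
#'   edge, with `u < v`.
#' @export
edge_list <- function(net) {
  idx <- which(upper.tri(net$adjacency) & net$adjacency == 1L, arr.ind = TRUE)
  colnames(idx) <- c("u", "v")
  idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
}

#' Remove one undirected edge
#'
#' @param net a [comm_network()].
#' @param edge length-2 vector of node indices or labels.
#' @return A new [comm_network()] without the edge.
#' @export
drop_edge <- function(net, edge) {
  ij <- resolve_edge(net, edge)
  A <- net$adjacency
  A[ij[1L], ij[2L]] <- 0L
  A[ij[2L], ij[1L]] <- 0L
  comm_network(A, labels = net$labels)
}

# map labels or indices to validated node indices of an existing edge
resolve_edge <- function(net, edge, must_exist = TRUE) {
  if (length(edge) != 2L) stop("an edge is a pair of nodes")
  if (is.character(edge)) {
    ij <- match(edge, net$labels)
    if (anyNA(ij)) stop("unknown node label in edge: ", paste(edge, collapse = ", "))
  } else {
    ij <- as.integer(edge)
    if (any(ij < 1L | ij > n_nodes(net))) stop("node index out of range")
  }
  if (must_exist && net$adjacency[ij[1L], ij[2L]] != 1L) {
    stop("edge {", edge[1L], ",", edge[2L], "} is not present in the network")
  }
  ij
}

# igraph view of a comm_network, optionally weighted
as_igraph <- function(net, weights = NULL) {
  if (is.null(weights)) {
    igraph::graph_from_adjacency_matrix(net$adjacency, mode = "undirected")
  } else {
    igraph::graph_from_adjacency_matrix(net$adjacency * weights,
                                        mode = "undirected", weighted = TRUE)
  }
}
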