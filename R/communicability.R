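#' Communicability matrix and subgraph centralities
#'
#' Computes the communicability matrix `G = exp(zeta * A)` of a binary
#' undirected network by symmetric eigendecomposition
#' `A = U L U'`, `G = U exp(zeta L) U'`. The entry `G[p, q]` weights all
#' walks from `p` to `q`, a walk of length `k` contributing `zeta^k / k!`;
#' the diagonal `G[p, p]` is the subgraph centrality of node `p` (the
#' "circulability" of a diffusing factor around it) and the off-diagonal
#' entries measure transmissibility between nodes.
#'
#' The eigendecomposition is kept on the returned object so the distance
#' matrix and spectral SI solutions reuse it.
#'
#' @param net a [comm_network()].
#' @param zeta positive real inverse-temperature-like parameter; default 1.
#' @return An object of class `comm_set` with fields `zeta`, `G`,
#'   `centralities`, eigendecomposition (`values`, `vectors`), and slots `X`
#'   and `W` that [communicability_distance()] and
#'   [communicability_weights()] populate.
#' @examples
#' net <- network_from_edges(cbind(1, 2), n_nodes = 2)
#' cs <- communicability_matrix(net)
#' cs$G         # cosh(1) on the diagonal, sinh(1) off it
#' @seealso [communicability()] for the one-call chain G -> X -> W.
#' @export
communicability_matrix <- function(net, zeta = 1) {
  stopifnot(inherits(net, "comm_network"))
  if (!is.numeric(zeta) || length(zeta) != 1L || !is.finite(zeta) || zeta <= 0) {
    stop("zeta must be a single positive number")
  }
  eig <- eigen(net$adjacency, symmetric = TRUE)
  G <- eig$vectors %*% (exp(zeta * eig$values) * t(eig$vectors))
  G <- (G + t(G)) / 2  # enforce exact symmetry against roundoff
  dimnames(G) <- list(net$labels, net$labels)
  structure(
    list(zeta = zeta, G = G, centralities = diag(G),
         values = eig$values, vectors = eig$vectors,
         X = NULL, W = NULL, labels = net$labels),
    class = "comm_set"
  )
}

#' Communicability distance matrix
#'
#' Populates the pairwise communicability distance
#' `X[p, q] = sqrt(G[p, p] + G[q, q] - 2 G[p, q])`, the Euclidean distance
#' between the nodes' positions in the spectral embedding
#' `x_p = exp(zeta * L / 2) U[p, ]`. Large values mean the diffusing factor
#' circulates at the two nodes rather than passing between them.
#'
#' @param cs a `comm_set` from [communicability_matrix()].
#' @param tol squared distances in `[-tol, 0)` are clipped to 0 (roundoff);
#'   anything below `-tol` raises an error, since it indicates a broken `G`.
#' @return `cs` with `X` populated (symmetric, zero diagonal, nonnegative).
#' @export
communicability_distance <- function(cs, tol = 1e-9) {
  stopifnot(inherits(cs, "comm_set"))
  d <- cs$centralities
  X2 <- outer(d, d, `+`) - 2 * cs$G
  if (any(X2 < -tol)) {
    stop("squared communicability distance below -", tol,
         " (min ", format(min(X2)), "): G is not a valid Gram-type matrix")
  }
  X2[X2 < 0] <- 0
  X <- sqrt(X2)
  X <- (X + t(X)) / 2
  diag(X) <- 0
  cs$X <- X
  cs
}

#' Communicability-weighted adjacency
#'
#' Populates `W = A * X` (entrywise): each existing edge carries its
#' communicability distance as weight, non-edges stay zero. Shortest
#' weighted paths on `W` are the shortest communicability paths.
#'
#' @param cs a `comm_set` with `X` populated.
#' @param net the [comm_network()] the set was computed from.
#' @return `cs` with `W` populated; `W > 0` exactly on the support of `A`.
#' @export
communicability_weights <- function(cs, net) {
  stopifnot(inherits(cs, "comm_set"), inherits(net, "comm_network"))
  if (is.null(cs$X)) stop("X not populated; call communicability_distance() first")
  if (nrow(cs$G) != n_nodes(net)) stop("network and comm_set dimensions differ")
  cs$W <- net$adjacency * cs$X
  cs
}

#' Full communicability set for a network
#'
#' Convenience chain: communicability matrix, distance matrix and weighted
#' adjacency in one call.
#'
#' @inheritParams communicability_matrix
#' @return A `comm_set` with `G`, `centralities`, `X` and `W` populated.
#' @examples
#' cs <- communicability(worked_example_graph())
#' cs$X["1", "6"]
#' @export
communicability <- function(net, zeta = 1) {
  cs <- communicability_matrix(net, zeta)
  cs <- communicability_distance(cs)
  communicability_weights(cs, net)
}

#' @export
print.comm_set <- function(x, ...) {
  cat("<comm_set> n = ", length(x$centralities), ", zeta = ", x$zeta,
      "; X ", if (is.null(x$X)) "not " else "", "populated",
      ", W ", if (is.null(x$W)) "not " else "", "populated\n", sep = "")
  invisible(x)
}
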