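# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: the matrix exponential is a truncated power
# series, and shortest paths are exhaustive enumeration over simple paths.

# e^(zeta*A) by direct series summation
expm_series <- function(A, zeta = 1, terms = 60L) {
  n <- nrow(A)
  acc <- diag(n)
  term <- diag(n)
  for (k in seq_len(terms)) {
    term <- term %*% (zeta * A) / k
    acc <- acc + term
  }
  unname(acc)
}

# minimum path weight between every pair by DFS over all simple paths;
# weights = NULL means hop counts. Only for small n.
brute_force_paths <- function(A, weights = NULL) {
  n <- nrow(A)
  best <- matrix(Inf, n, n)
  diag(best) <- 0
  nbrs <- lapply(seq_len(n), function(i) which(A[i, ] > 0))
  dfs <- function(node, target, visited, acc) {
    if (node == target) {
      if (acc < best[start, target]) best[start, target] <<- acc
      return(invisible(NULL))
    }
    for (k in nbrs[[node]]) {
      if (!visited[k]) {
        w <- if (is.null(weights)) 1 else weights[node, k]
        if (acc + w < best[start, target]) {
          visited[k] <- TRUE
          dfs(k, target, visited, acc + w)
          visited[k] <- FALSE
        }
      }
    }
    invisible(NULL)
  }
  for (start in seq_len(n - 1L)) {
    for (target in seq(start + 1L, n)) {
      visited <- rep(FALSE, n)
      visited[start] <- TRUE
      dfs(start, target, visited, 0)
      best[target, start] <- best[start, target]
    }
  }
  best
}

# seeded random connected comm_network for property loops
random_connected_net <- function(n, p = 0.5, seed) {
  random_graph(n, "erdos_renyi", p = p, connected = TRUE, seed = seed)
}

# small deterministic nets used in several files
net_k2 <- function() network_from_edges(cbind(1, 2), n_nodes = 2)
net_p3 <- function() network_from_edges(rbind(c(1, 2), c(2, 3)), n_nodes = 3)
net_k3 <- function() network_from_edges(rbind(c(1, 2), c(2, 3), c(1, 3)), n_nodes = 3)
net_edgeless <- function(n) comm_network(matrix(0, n, n))
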