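#' The 9-node worked-example graph
#'
#' A small bridgeless graph on nodes 1..9 used throughout as a worked
#' example: the shortest *topological* path between nodes 1 and 6 is the
#' 3-hop route 1-2-4-6 through the dense cluster \{2,3,4,5\}, but the
#' shortest *communicability* path is the longer peripheral route
#' 1-9-8-7-6, because edges inside the cluster carry large communicability
#' distances. Every edge is cyclic. Shipped as a versioned edge-list
#' fixture under `inst/extdata/`; its transcription is pinned by the
#' package tests to the worked-example values (edge-averaged distance
#' 2.4797, normalized path lengths 1.939 and 2.049).
#'
#' @return A [comm_network()] with 9 nodes and 12 edges.
#' @examples
#' net <- worked_example_graph()
#' extract_path(shortest_topological_paths(net), "1", "6")
#' @export
worked_example_graph <- function() {
  path <- system.file("extdata", "worked_example_edges.tsv", package = "commgeom")
  el <- utils::read.delim(path)
  network_from_edges(as.matrix(el), n_nodes = 9L,
                     labels = as.character(1:9), one_based = TRUE)
}

#' Seeded random graphs
#'
#' Reproducible random graph generation for simulation studies. Supported
#' models: Erdos-Renyi `G(n, p)` and random geometric graphs on the unit
#' square (nodes within `radius` connected).
#'
#' @param n number of nodes.
#' @param model `"erdos_renyi"` or `"geometric"`.
#' @param p connection probability (Erdos-Renyi).
#' @param radius connection radius (geometric).
#' @param connected if `TRUE`, resample until the graph is connected.
#' @param seed integer seed; required, so every graph is reproducible.
#' @param max_tries resampling cap when `connected = TRUE`.
#' @return A [comm_network()].
#' @export
random_graph <- function(n, model = c("erdos_renyi", "geometric"), p = NULL,
                         radius = NULL, connected = FALSE, seed,
                         max_tries = 100L) {
  model <- match.arg(model)
  if (missing(seed)) stop("a seed is required for reproducibility")
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(seed)
  for (k in seq_len(max_tries)) {
    g <- switch(model,
      erdos_renyi = {
        if (is.null(p)) stop("erdos_renyi needs p")
        igraph::sample_gnp(n, p)
      },
      geometric = {
        if (is.null(radius)) stop("geometric needs radius")
        xy <- matrix(stats::runif(2 * n), ncol = 2)
        A <- as.matrix(stats::dist(xy)) < radius
        diag(A) <- FALSE
        igraph::graph_from_adjacency_matrix(A, mode = "undirected")
      })
    if (!connected || igraph::is_connected(g)) {
      A <- as.matrix(igraph::as_adjacency_matrix(g))
      return(comm_network(A))
    }
  }
  stop("failed to draw a connected graph in ", max_tries, " tries; ",
       "increase density or max_tries")
}

#' Specification of a synthetic two-group cohort
#'
#' Describes a cohort of binary symmetric "connectomes" with a planted
#' between-group difference: every subject is a noisy copy of a common base
#' graph; in the disease-like group a fixed set of base edges is removed
#' before the noise is applied. Subject noise flips each node pair
#' independently (present edges vanish, absent pairs appear) with the given
#' probability, emulating per-subject tractography variability.
#'
#' Defaults define the package's reference simulation condition: a
#' connected Erdos-Renyi base graph with `n = 60` nodes and edge
#' probability 0.15 (mean degree about 9, in the range of thresholded
#' connectomes), 20 subjects per group, 12 planted edge removals and flip
#' probability 0.02.
#'
#' @param n_nodes nodes per subject.
#' @param n_per_group length-2 integer vector: subjects in the healthy-like
#'   and disease-like group.
#' @param model,p,radius base-graph model, as in [random_graph()].
#' @param n_planted number of base edges removed in the disease-like group;
#'   chosen (seeded) among edges whose removal keeps the base connected.
#' @param subject_noise per-pair flip probability in `[0, 0.5)`.
#' @param node_tag_scheme `"halves_vermis"` assigns the first and second
#'   ~45% of nodes to `left`/`right` and the remainder to `vermis`;
#'   or a character vector of per-node tags.
#' @param seed integer seed for base graph, planted set and subject noise.
#' @return A `cohort_spec` object.
#' @export
cohort_spec <- function(n_nodes = 60L, n_per_group = c(20L, 20L),
                        model = "erdos_renyi", p = 0.15, radius = NULL,
                        n_planted = 12L, subject_noise = 0.02,
                        node_tag_scheme = "halves_vermis", seed = 42L) {
  if (subject_noise < 0 || subject_noise >= 0.5) stop("subject_noise must be in [0, 0.5)")
  if (any(n_per_group < 2L)) stop("need at least 2 subjects per group")
  structure(list(n_nodes = as.integer(n_nodes),
                 n_per_group = as.integer(n_per_group),
                 model = model, p = p, radius = radius,
                 n_planted = as.integer(n_planted),
                 subject_noise = subject_noise,
                 node_tag_scheme = node_tag_scheme,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Generate a synthetic two-group cohort
#'
#' Draws the base graph, plants the group difference and emits per-subject
#' weighted matrices (weight 1 for present edges, so the binarization stage
#' of the pipeline is exercised). The ground-truth planted pair list is
#' attached for recovery scoring.
#'
#' @param spec a [cohort_spec()].
#' @return A `cohort` object (see [cohort()]) with extra fields
#'   `base_network` and `planted_pairs` (k x 2 integer matrix).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  base <- random_graph(spec$n_nodes, model = spec$model, p = spec$p,
                       radius = spec$radius, connected = TRUE,
                       seed = spec$seed)
  set.seed(spec$seed + 1L)
  planted <- choose_planted_edges(base, spec$n_planted)
  n <- spec$n_nodes
  A_h <- base$adjacency
  A_d <- A_h
  if (nrow(planted) > 0) {
    A_d[planted] <- 0L
    A_d[planted[, c(2L, 1L), drop = FALSE]] <- 0L
  }
  labels <- base$labels
  n_h <- spec$n_per_group[1L]
  n_d <- spec$n_per_group[2L]
  flip <- function(A) {
    # symmetric Bernoulli flips on the upper triangle
    up <- upper.tri(A)
    f <- stats::rbinom(sum(up), 1L, spec$subject_noise)
    M <- matrix(0L, n, n)
    M[up] <- f
    M <- M + t(M)
    out <- abs(A - M)
    dimnames(out) <- dimnames(A)
    out
  }
  subjects <- c(
    lapply(seq_len(n_h), function(k) flip(A_h) * 1.0),
    lapply(seq_len(n_d), function(k) flip(A_d) * 1.0)
  )
  names(subjects) <- c(sprintf("H%02d", seq_len(n_h)), sprintf("D%02d", seq_len(n_d)))
  tags <- node_tags(spec$node_tag_scheme, n)
  ch <- cohort(subjects, groups = rep(c("group_H", "group_D"), c(n_h, n_d)),
               node_labels = labels, node_tags = tags)
  ch$base_network <- base
  ch$planted_pairs <- planted
  ch
}

# sample edges whose sequential removal keeps the base graph connected
choose_planted_edges <- function(base, k) {
  el <- edge_list(base)
  if (k == 0L) return(el[0, , drop = FALSE])
  order <- sample(nrow(el))
  cur <- base
  chosen <- integer(0)
  for (idx in order) {
    if (length(chosen) >= k) break
    e <- el[idx, ]
    if (is_cyclic_edge(cur, e)) {
      cur <- drop_edge(cur, e)
      chosen <- c(chosen, idx)
    }
  }
  if (length(chosen) < k) {
    stop("could not find ", k, " removable edges keeping the base connected")
  }
  el[sort(chosen), , drop = FALSE]
}

node_tags <- function(scheme, n) {
  if (length(scheme) == n && !identical(scheme, "halves_vermis")) {
    return(as.character(scheme))
  }
  if (!identical(scheme, "halves_vermis")) stop("unknown node_tag_scheme")
  n_side <- floor(0.45 * n)
  c(rep("left", n_side), rep("right", n_side),
    rep("vermis", n - 2L * n_side))
}

# save/restore the caller's RNG state so seeded generators do not disturb it
get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
  invisible(NULL)
}
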