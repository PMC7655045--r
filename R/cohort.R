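#' Two-group cohort of connectivity matrices
#'
#' Container for a group comparison: one square nonnegative connectivity
#' matrix per subject, a group label per subject, and node metadata.
#'
#' @param subjects named list of square nonnegative matrices, all of the
#'   same dimension.
#' @param groups character vector of group memberships, one per subject;
#'   exactly two distinct groups, each with at least two subjects. The
#'   *first* level (default `"group_H"`) plays the reference role: its mean
#'   binarized adjacency defines the threshold mask and observed
#'   differences are reference-minus-other.
#' @param node_labels character vector of region names.
#' @param node_tags optional per-node category (e.g. `left`/`right`/
#'   `vermis`) used by [classify_significant_pairs()].
#' @param group_levels length-2 character vector fixing which group is the
#'   reference; defaults to `c("group_H", "group_D")` when those labels are
#'   used, otherwise to the sorted unique labels.
#' @return A `cohort` object.
#' @export
cohort <- function(subjects, groups, node_labels = NULL, node_tags = NULL,
                   group_levels = NULL) {
  if (!is.list(subjects) || length(subjects) < 4L) {
    stop("need a list of at least 4 subject matrices (2 per group)")
  }
  dims <- vapply(subjects, function(m) dim(as.matrix(m)), integer(2))
  if (length(unique(dims[1, ])) != 1L || any(dims[1, ] != dims[2, ])) {
    stop("all subject matrices must be square and of the same dimension")
  }
  n <- dims[1, 1]
  if (any(vapply(subjects, function(m) any(m < 0), logical(1)))) {
    stop("connectivity matrices must be nonnegative")
  }
  if (length(groups) != length(subjects)) stop("one group label per subject")
  lev <- unique(groups)
  if (length(lev) != 2L) stop("exactly two groups are required")
  if (is.null(group_levels)) {
    group_levels <- if (setequal(lev, c("group_H", "group_D"))) {
      c("group_H", "group_D")
    } else sort(lev)
  }
  if (!setequal(group_levels, lev)) stop("group_levels must match the labels used")
  if (min(table(groups)) < 2L) stop("each group needs at least 2 subjects")
  if (is.null(node_labels)) node_labels <- paste0("v", seq_len(n))
  if (is.null(names(subjects))) names(subjects) <- sprintf("S%03d", seq_along(subjects))
  structure(list(subjects = lapply(subjects, as.matrix), groups = groups,
                 group_levels = group_levels,
                 node_labels = as.character(node_labels),
                 node_tags = node_tags),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  tab <- table(x$groups)
  cat("<cohort> ", length(x$subjects), " subjects (",
      paste(names(tab), tab, sep = ": ", collapse = ", "), "), ",
      length(x$node_labels), " nodes\n", sep = "")
  invisible(x)
}

#' Binarize a connectivity matrix
#'
#' Entry 1 iff the weight is strictly positive; the result is symmetrized
#' by maximum and the diagonal forced to zero.
#'
#' @param m square nonnegative matrix.
#' @return Binary integer adjacency matrix.
#' @export
binarize_subject <- function(m) {
  m <- as.matrix(m)
  if (nrow(m) != ncol(m)) stop("matrix must be square")
  if (any(m < 0)) stop("negative entries are not a valid connectivity matrix")
  A <- (m > 0) * 1L
  A <- pmax(A, t(A))
  diag(A) <- 0L
  A
}

#' Threshold a cohort through the reference-group mask
#'
#' Binarizes every subject, computes the edge frequency matrix of the
#' reference group (entries in `[0, 1]`: the fraction of reference subjects
#' in which each edge occurs), keeps edges with frequency strictly above
#' `tau`, and projects every subject's adjacency onto this mask. Nodes left
#' isolated *in the mask* are dropped from all subjects so downstream
#' graphs have no structurally isolated nodes.
#'
#' @param ch a [cohort()].
#' @param tau threshold in `[0, 0.9]`.
#' @return A `masked_cohort`: `tau`, `mask` (binary, on kept nodes),
#'   `adjacencies` (per-subject binary matrices), `groups`,
#'   `group_levels`, `node_labels`, `node_tags`, `dropped_nodes` (labels).
#' @export
build_group_mask <- function(ch, tau) {
  stopifnot(inherits(ch, "cohort"))
  if (!is.numeric(tau) || length(tau) != 1L || tau < 0 || tau > 0.9) {
    stop("tau must lie in [0, 0.9]")
  }
  bins <- lapply(ch$subjects, binarize_subject)
  ref <- ch$groups == ch$group_levels[1L]
  freq <- Reduce(`+`, bins[ref]) / sum(ref)
  mask <- (freq > tau) * 1L
  keep <- rowSums(mask) > 0
  if (!any(keep)) stop("mask has no edges at tau = ", tau)
  dropped <- ch$node_labels[!keep]
  mask <- mask[keep, keep, drop = FALSE]
  adjacencies <- lapply(bins, function(A) A[keep, keep, drop = FALSE] * mask)
  structure(list(tau = tau, mask = mask, adjacencies = adjacencies,
                 groups = ch$groups, group_levels = ch$group_levels,
                 node_labels = ch$node_labels[keep],
                 node_tags = if (is.null(ch$node_tags)) NULL else ch$node_tags[keep],
                 dropped_nodes = dropped),
            class = "masked_cohort")
}

#' @export
print.masked_cohort <- function(x, ...) {
  cat("<masked_cohort> tau = ", x$tau, ", ", length(x$node_labels),
      " nodes kept (", length(x$dropped_nodes), " dropped), ",
      sum(x$mask) / 2, " mask edges\n", sep = "")
  invisible(x)
}

#' Per-subject path-length measure matrices
#'
#' For every subject of a masked cohort, computes the chosen pairwise
#' measure: `"normalized_communicability"` (shortest communicability path
#' lengths divided by that subject's own edge-averaged communicability
#' distance — unitless, density-adjusted), `"communicability"`
#' (unnormalized lengths) or `"topological"` (hop counts).
#'
#' @param mc a [build_group_mask()] result.
#' @param measure which pairwise measure to compute.
#' @param zeta communicability parameter.
#' @return List of n x n matrices, one per subject (`Inf` across
#'   components).
#' @export
subject_measure_matrices <- function(mc,
                                     measure = c("normalized_communicability",
                                                 "communicability", "topological"),
                                     zeta = 1) {
  stopifnot(inherits(mc, "masked_cohort"))
  measure <- match.arg(measure)
  lapply(mc$adjacencies, function(A) {
    net <- comm_network(A, labels = mc$node_labels)
    if (measure == "topological") {
      shortest_topological_paths(net)$lengths
    } else {
      cs <- communicability(net, zeta)
      pl <- shortest_communicability_paths(cs)
      if (measure == "communicability") {
        pl$lengths
      } else {
        normalize_path_lengths(pl, mean_edge_comm_distance(cs, net))$s_hat
      }
    }
  })
}

#' Permutation test for group differences per node pair
#'
#' For every node pair, the observed difference is the reference-group mean
#' minus the other group's mean of the chosen measure. The null
#' distribution is built by reassigning subjects to two groups of the
#' original sizes `n_perm` times; the two-sided p-value uses the add-one
#' estimator `p = (1 + #{|d_rand| >= |d_obs|}) / (1 + n_perm)`, which is
#' never zero. Pairs with an infinite measure in any subject are excluded
#' from testing (their count is reported), since a cross-component length
#' has no magnitude to compare.
#'
#' @param mc a [build_group_mask()] result.
#' @param measure passed to [subject_measure_matrices()].
#' @param zeta communicability parameter.
#' @param n_perm number of label permutations (>= 100).
#' @param alpha significance level for the corrected flags.
#' @param seed integer seed (mandatory: permutations must be reproducible).
#' @return A `permutation_result`: `observed_delta`, `p_values` (both n x n
#'   symmetric, `NA` at untested pairs), `significant_fdr`,
#'   `significant_bonferroni` (logical matrices), `n_excluded_pairs`,
#'   `n_permutations`, `alpha`, `seed`, `measure`, `node_tags`.
#' @export
permutation_test <- function(mc, measure = "normalized_communicability",
                             zeta = 1, n_perm = 1000L, alpha = 0.05, seed) {
  stopifnot(inherits(mc, "masked_cohort"))
  if (missing(seed)) stop("a seed is required")
  if (n_perm < 100L) stop("n_perm must be at least 100")
  mats <- subject_measure_matrices(mc, measure, zeta)
  n <- length(mc$node_labels)
  up <- which(upper.tri(matrix(0, n, n)))
  V <- do.call(rbind, lapply(mats, function(M) M[up]))  # subjects x pairs
  ref <- mc$groups == mc$group_levels[1L]
  n_ref <- sum(ref)
  n_oth <- sum(!ref)
  testable <- colSums(!is.finite(V)) == 0
  obs <- colMeans(V[ref, , drop = FALSE]) - colMeans(V[!ref, , drop = FALSE])
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(seed)
  n_sub <- nrow(V)
  # contrast weights: +1/n_ref on permuted reference, -1/n_oth on the rest
  Wp <- matrix(-1 / n_oth, n_perm, n_sub)
  for (b in seq_len(n_perm)) Wp[b, sample(n_sub, n_ref)] <- 1 / n_ref
  Vt <- V[, testable, drop = FALSE]
  null_delta <- Wp %*% Vt
  exceed <- colSums(abs(null_delta) >= rep(abs(obs[testable]), each = n_perm))
  p_test <- (1 + exceed) / (1 + n_perm)
  p_vec <- rep(NA_real_, length(up))
  p_vec[testable] <- p_test
  obs[!testable] <- NA_real_
  labels <- mc$node_labels
  to_mat <- function(v) {
    M <- matrix(NA_real_, n, n, dimnames = list(labels, labels))
    M[up] <- v
    M[lower.tri(M)] <- t(M)[lower.tri(M)]
    M
  }
  p_values <- to_mat(p_vec)
  structure(list(
    observed_delta = to_mat(obs),
    p_values = p_values,
    significant_fdr = adjust_pvalues(p_values, "fdr", alpha),
    significant_bonferroni = adjust_pvalues(p_values, "bonferroni", alpha),
    n_excluded_pairs = sum(!testable),
    n_permutations = as.integer(n_perm),
    alpha = alpha, seed = as.integer(seed), measure = measure,
    node_tags = mc$node_tags
  ), class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  up <- upper.tri(x$p_values)
  cat("<permutation_result> measure = ", x$measure, ", ",
      sum(!is.na(x$p_values[up])), " pairs tested (",
      x$n_excluded_pairs, " excluded), ", x$n_permutations,
      " permutations\n  significant: FDR ",
      sum(x$significant_fdr[up], na.rm = TRUE), ", Bonferroni ",
      sum(x$significant_bonferroni[up], na.rm = TRUE),
      " at alpha = ", x$alpha, "\n", sep = "")
  invisible(x)
}

#' Multiple-testing correction over node pairs
#'
#' Applies Benjamini-Hochberg FDR or Bonferroni control to the upper
#' triangle of a symmetric p-value matrix; `NA` entries (untested pairs)
#' are skipped and stay `NA` in the output. `kappa`, the number of
#' comparisons, is the number of tested pairs.
#'
#' Boundary semantics follow each rule's classical statement: the BH
#' step-up keeps `p_(k) <= alpha * k / kappa` (adjusted p equal to `alpha`
#' is significant), while Bonferroni uses the strict `p < alpha / kappa`.
#'
#' @param p_matrix symmetric matrix of p-values in `(0, 1]`, `NA` allowed.
#' @param method `"fdr"` (Benjamini-Hochberg, the default reading of FDR),
#'   `"by"` (Benjamini-Yekutieli) or `"bonferroni"`.
#' @param alpha level of the correction.
#' @return Symmetric logical matrix of significance flags.
#' @export
adjust_pvalues <- function(p_matrix, method = c("fdr", "bonferroni", "by"),
                           alpha = 0.05) {
  method <- match.arg(method)
  p_matrix <- as.matrix(p_matrix)
  up <- which(upper.tri(p_matrix))
  p <- p_matrix[up]
  ok <- !is.na(p)
  if (any(p[ok] <= 0 | p[ok] > 1)) stop("p-values must lie in (0, 1]")
  sig <- rep(NA, length(p))
  sig[ok] <- switch(method,
    fdr = stats::p.adjust(p[ok], method = "BH") <= alpha,
    by = stats::p.adjust(p[ok], method = "BY") <= alpha,
    bonferroni = p[ok] < alpha / sum(ok)
  )
  out <- matrix(NA, nrow(p_matrix), ncol(p_matrix), dimnames = dimnames(p_matrix))
  out[up] <- sig
  out[lower.tri(out)] <- t(out)[lower.tri(out)]
  diag(out) <- FALSE
  out
}

#' Classify significant pairs by node category and sign
#'
#' Cross-tabulates the significant node pairs by the category of their
#' endpoints (`left-left`, `right-right`, `left-right`, `vermis-left`,
#' `vermis-right`, `vermis-vermis` as applicable) and by the sign of the
#' observed difference: `delta > 0` means the measure *decreased* in the
#' non-reference group's... i.e. is larger in the reference group mean.
#'
#' @param pr a [permutation_test()] result.
#' @param node_tags per-node categories; defaults to the tags carried by
#'   `pr`.
#' @param correction which significance flags to use.
#' @return Data frame with columns `category`, `n_delta_pos`,
#'   `n_delta_neg`, `n_total`, `fraction` (of all significant pairs).
#' @export
classify_significant_pairs <- function(pr, node_tags = NULL,
                                       correction = c("fdr", "bonferroni")) {
  stopifnot(inherits(pr, "permutation_result"))
  correction <- match.arg(correction)
  if (is.null(node_tags)) node_tags <- pr$node_tags
  if (is.null(node_tags)) stop("no node tags available")
  n <- nrow(pr$p_values)
  if (length(node_tags) != n) stop("need one tag per node")
  sig <- if (correction == "fdr") pr$significant_fdr else pr$significant_bonferroni
  idx <- which(upper.tri(sig) & !is.na(sig) & sig, arr.ind = TRUE)
  tags <- sort(unique(node_tags))
  cats <- outer(tags, tags, function(a, b) paste(pmin(a, b), pmax(a, b), sep = "-"))
  cats <- sort(unique(cats[upper.tri(cats, diag = TRUE)]))
  count <- function(rows) {
    tab <- stats::setNames(numeric(length(cats)), cats)
    if (length(rows) > 0) {
      key <- paste(pmin(node_tags[idx[rows, 1L]], node_tags[idx[rows, 2L]]),
                   pmax(node_tags[idx[rows, 1L]], node_tags[idx[rows, 2L]]),
                   sep = "-")
      t2 <- table(key)
      tab[names(t2)] <- as.numeric(t2)
    }
    tab
  }
  delta <- pr$observed_delta[idx]
  pos <- count(which(delta > 0))
  neg <- count(which(delta < 0))
  total <- pos + neg + count(which(delta == 0))
  data.frame(category = cats,
             n_delta_pos = as.integer(pos),
             n_delta_neg = as.integer(neg),
             n_total = as.integer(total),
             fraction = if (sum(total) > 0) total / sum(total) else rep(0, length(cats)),
             row.names = NULL)
}

#' Per-node median profile of a difference matrix
#'
#' For each node, the median of the finite off-diagonal entries of its row;
#' summarizes whether a region's path lengths to the rest of the network
#' mostly increased or decreased.
#'
#' @param delta_matrix square symmetric matrix (e.g. `observed_delta`).
#' @return Named numeric vector of per-node medians (`NA` where a row has
#'   no finite off-diagonal entries).
#' @export
node_median_profile <- function(delta_matrix) {
  delta_matrix <- as.matrix(delta_matrix)
  n <- nrow(delta_matrix)
  if (n != ncol(delta_matrix)) stop("matrix must be square")
  out <- vapply(seq_len(n), function(i) {
    v <- delta_matrix[i, -i]
    v <- v[is.finite(v)]
    if (length(v) == 0) NA_real_ else stats::median(v)
  }, numeric(1))
  names(out) <- rownames(delta_matrix)
  out
}

#' Fraction of significant pairs across thresholds
#'
#' Runs the full mask-measure-permutation pipeline at each `tau` and
#' reports the fraction of tested pairs flagged significant, for one or
#' more measures — the sensitivity-versus-threshold curve.
#'
#' @param ch a [cohort()].
#' @param taus thresholds to scan.
#' @param measures measures to compare.
#' @param zeta,n_perm,alpha,seed passed to [permutation_test()].
#' @return Data frame: `tau`, `measure`, `n_tested`, `n_fdr`, `n_bonf`,
#'   `frac_fdr`, `frac_bonf`.
#' @export
tau_sweep <- function(ch, taus = seq(0, 0.9, by = 0.1),
                      measures = c("normalized_communicability", "topological"),
                      zeta = 1, n_perm = 1000L, alpha = 0.05, seed) {
  stopifnot(inherits(ch, "cohort"))
  if (missing(seed)) stop("a seed is required")
  rows <- list()
  for (tau in taus) {
    mc <- build_group_mask(ch, tau)
    for (ms in measures) {
      pr <- permutation_test(mc, measure = ms, zeta = zeta,
                             n_perm = n_perm, alpha = alpha, seed = seed)
      up <- upper.tri(pr$p_values)
      n_tested <- sum(!is.na(pr$p_values[up]))
      n_fdr <- sum(pr$significant_fdr[up], na.rm = TRUE)
      n_bonf <- sum(pr$significant_bonferroni[up], na.rm = TRUE)
      rows[[length(rows) + 1L]] <- data.frame(
        tau = tau, measure = ms, n_tested = n_tested,
        n_fdr = n_fdr, n_bonf = n_bonf,
        frac_fdr = n_fdr / n_tested, frac_bonf = n_bonf / n_tested)
    }
  }
  do.call(rbind, rows)
}

#' Recall of planted pairs
#'
#' Fraction of a ground-truth pair list (e.g. the planted removed edges of
#' [generate_cohort()]) flagged significant. Pair indices refer to the
#' cohort's original node order and are mapped through any node dropping.
#'
#' @param pr a [permutation_test()] result.
#' @param planted_pairs k x 2 matrix of node indices in the original
#'   cohort order.
#' @param original_labels node labels of the original (unmasked) cohort.
#' @param correction which flags to score.
#' @return Scalar recall in `[0, 1]`, with attribute `n_found`.
#' @export
planted_recall <- function(pr, planted_pairs, original_labels,
                           correction = c("fdr", "bonferroni")) {
  stopifnot(inherits(pr, "permutation_result"))
  correction <- match.arg(correction)
  sig <- if (correction == "fdr") pr$significant_fdr else pr$significant_bonferroni
  kept <- rownames(sig)
  i <- match(original_labels[planted_pairs[, 1L]], kept)
  j <- match(original_labels[planted_pairs[, 2L]], kept)
  hit <- mapply(function(a, b) {
    if (is.na(a) || is.na(b)) return(FALSE)
    isTRUE(sig[a, b])
  }, i, j)
  out <- mean(hit)
  attr(out, "n_found") <- sum(hit)
  out
}
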