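# small deterministic cohort helper: k subjects per group around a base net
toy_cohort <- function(base, k = 3, planted = NULL, seed = 1) {
  A_h <- base$adjacency * 1.0
  A_d <- A_h
  if (!is.null(planted)) {
    A_d[planted] <- 0
    A_d[planted[, c(2, 1), drop = FALSE]] <- 0
  }
  subjects <- c(replicate(k, A_h, simplify = FALSE),
                replicate(k, A_d, simplify = FALSE))
  names(subjects) <- c(paste0("H", 1:k), paste0("D", 1:k))
  cohort(subjects, groups = rep(c("group_H", "group_D"), each = k),
         node_labels = base$labels)
}

test_that("binarization is strict, symmetrizing and diagonal-clearing", {
  expect_equal(binarize_subject(matrix(0, 3, 3)), matrix(0L, 3, 3))
  m <- matrix(0, 3, 3)
  m[1, 2] <- 0.7
  B <- binarize_subject(m)
  expect_equal(B[2, 1], 1L)   # symmetrized by max
  expect_equal(sum(B), 2L)    # exactly one undirected edge; zeros stay zero
  diag(m) <- 5
  expect_true(all(diag(binarize_subject(m)) == 0))
  expect_error(binarize_subject(matrix(-1, 2, 2)), "negative")
})

test_that("group mask uses strict frequency threshold on the reference group", {
  base <- random_connected_net(8, p = 0.6, seed = 31)
  ch <- toy_cohort(base, k = 4)
  # give edge (1,2) frequency 0.5 in group H
  stopifnot(base$adjacency[1, 2] == 1)
  ch$subjects[[1]][1, 2] <- ch$subjects[[1]][2, 1] <- 0
  ch$subjects[[2]][1, 2] <- ch$subjects[[2]][2, 1] <- 0
  mc_040 <- build_group_mask(ch, 0.4)
  mc_050 <- build_group_mask(ch, 0.5)
  expect_equal(mc_040$mask["v1", "v2"], 1L)  # 0.5 > 0.4
  expect_equal(mc_050$mask["v1", "v2"], 0L)  # strict: 0.5 > 0.5 is FALSE
  # tau = 0 keeps any edge present in at least one reference subject
  mc0 <- build_group_mask(ch, 0)
  expect_equal(unname(mc0$mask), unname((Reduce(`+`,
    lapply(ch$subjects[1:4], binarize_subject)) > 0) * 1L))
  expect_error(build_group_mask(ch, 1.0), "0, 0.9")
})

test_that("nodes isolated in the mask are dropped from all subjects", {
  base <- net_p3()
  ch <- toy_cohort(base, k = 2)
  # remove both edges at node 3 in every reference subject
  for (i in 1:2) ch$subjects[[i]][3, ] <- ch$subjects[[i]][, 3] <- 0
  mc <- build_group_mask(ch, 0)
  expect_equal(mc$dropped_nodes, "v3")
  expect_equal(dim(mc$mask), c(2L, 2L))
  expect_true(all(vapply(mc$adjacencies, nrow, integer(1)) == 2L))
})

test_that("subject measures: identical subjects give identical matrices, hats are unitless", {
  base <- random_connected_net(7, p = 0.6, seed = 32)
  ch <- toy_cohort(base, k = 2)
  mc <- build_group_mask(ch, 0)
  mats <- subject_measure_matrices(mc, "normalized_communicability")
  expect_equal(mats[[1]], mats[[2]])
  expect_equal(mats[[1]], mats[[4]])
  topo <- subject_measure_matrices(mc, "topological")
  net <- comm_network(mc$adjacencies[[1]], labels = mc$node_labels)
  expect_equal(topo[[1]], shortest_topological_paths(net)$lengths)
  # the normalized matrix equals lengths / own xi_bar
  cs <- communicability(net)
  pl <- shortest_communicability_paths(cs)
  expect_equal(mats[[1]], pl$lengths / mean_edge_comm_distance(cs, net))
})

test_that("BH and Bonferroni corrections match hand application", {
  p <- c(0.001, 0.011, 0.021, 0.04, 0.9)
  # embed in a symmetric matrix upper triangle (n = 4 gives 6 slots)
  M <- matrix(NA_real_, 4, 4)
  M[upper.tri(M)] <- c(p, NA)
  M[lower.tri(M)] <- t(M)[lower.tri(M)]
  bh <- adjust_pvalues(M, "fdr", 0.05)
  bf <- adjust_pvalues(M, "bonferroni", 0.05)
  got_bh <- bh[upper.tri(bh)][1:5]
  got_bf <- bf[upper.tri(bf)][1:5]
  # BH step-up by hand over 5 tests: largest k with p_(k) <= 0.05 k / 5 is 4
  expect_equal(got_bh, c(TRUE, TRUE, TRUE, TRUE, FALSE))
  # Bonferroni: p < 0.05 / 5 keeps only 0.001
  expect_equal(got_bf, c(TRUE, FALSE, FALSE, FALSE, FALSE))
  # single test: both reduce to p < alpha
  M1 <- matrix(c(NA, 0.04, 0.04, NA), 2)
  expect_true(adjust_pvalues(M1, "fdr")[1, 2])
  expect_true(adjust_pvalues(M1, "bonferroni")[1, 2])
  # all p = 1: nothing significant
  Mall <- matrix(1, 3, 3)
  expect_false(any(adjust_pvalues(Mall, "fdr")[upper.tri(Mall)]))
})

test_that("permutation test is reproducible, order-invariant, and nests corrections", {
  spec <- cohort_spec(n_nodes = 24L, n_per_group = c(8L, 8L), n_planted = 4L,
                      seed = 5L)
  ch <- generate_cohort(spec)
  mc <- build_group_mask(ch, 0.3)
  pr1 <- permutation_test(mc, n_perm = 200L, seed = 9L)
  pr2 <- permutation_test(mc, n_perm = 200L, seed = 9L)
  expect_identical(pr1$p_values, pr2$p_values)
  # subject order must not matter (same seed: same label reassignments act
  # on the same multiset of matrices)
  perm <- c(9:16, 1:8)
  mc_shuf <- mc
  mc_shuf$adjacencies <- mc$adjacencies[perm]
  mc_shuf$groups <- mc$groups[perm]
  pr3 <- permutation_test(mc_shuf, n_perm = 200L, seed = 9L)
  # labels stayed attached to their subjects, so the observed contrast is identical
  expect_equal(pr3$observed_delta, pr1$observed_delta)
  # nesting at equal alpha
  up <- upper.tri(pr1$p_values)
  expect_true(all(!pr1$significant_bonferroni[up] | pr1$significant_fdr[up],
                  na.rm = TRUE))
  expect_error(permutation_test(mc, n_perm = 50L, seed = 1L), "at least 100")
})

test_that("p-values respect the permutation resolution bound", {
  spec <- cohort_spec(n_nodes = 20L, n_per_group = c(6L, 6L), n_planted = 3L,
                      seed = 6L)
  ch <- generate_cohort(spec)
  mc <- build_group_mask(ch, 0.3)
  pr <- permutation_test(mc, n_perm = 100L, seed = 2L)
  p <- pr$p_values[upper.tri(pr$p_values)]
  expect_true(all(p >= 1 / 101, na.rm = TRUE))
  # with min attainable p = 1/101 > alpha / n_pairs, Bonferroni is empty
  n_pairs <- sum(!is.na(p))
  stopifnot(1 / 101 > 0.05 / n_pairs)
  expect_false(any(pr$significant_bonferroni[upper.tri(pr$p_values)], na.rm = TRUE))
})

test_that("pair classification counts categories split by delta sign", {
  pv <- matrix(1, 4, 4)
  dimnames(pv) <- list(letters[1:4], letters[1:4])
  pr <- structure(list(
    p_values = pv,
    observed_delta = matrix(c(0, 2, -1, 0, 2, 0, 0, 0, -1, 0, 0, 0, 0, 0, 0, 0),
                            4, 4, dimnames = dimnames(pv)),
    significant_fdr = matrix(c(FALSE, TRUE, TRUE, FALSE, TRUE, FALSE, FALSE,
                               FALSE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE,
                               FALSE, FALSE), 4, 4, dimnames = dimnames(pv)),
    significant_bonferroni = matrix(FALSE, 4, 4, dimnames = dimnames(pv)),
    node_tags = c("left", "right", "left", "vermis")
  ), class = "permutation_result")
  tab <- classify_significant_pairs(pr)
  expect_equal(tab$n_total[tab$category == "left-right"], 1L)
  expect_equal(tab$n_delta_pos[tab$category == "left-right"], 1L)
  expect_equal(tab$n_total[tab$category == "left-left"], 1L)
  expect_equal(tab$n_delta_neg[tab$category == "left-left"], 1L)
  expect_equal(sum(tab$n_total), 2L)
  expect_equal(sum(tab$fraction), 1)
  # no significant pairs: all-zero table
  pr$significant_fdr[] <- FALSE
  expect_equal(sum(classify_significant_pairs(pr)$n_total), 0L)
})

test_that("node medians are robust and recover planted row-sign structure", {
  expect_equal(unname(node_median_profile(matrix(3, 3, 3))), rep(3, 3))
  M <- rbind(c(0, 1, 2, 100), c(1, 0, 2, 100), c(2, 2, 0, 100), c(100, 100, 100, 0))
  expect_equal(unname(node_median_profile(M))[1], 2)  # median of (1, 2, 100)
  # antisymmetric planted pattern: positive rows vs negative rows
  n <- 10
  D <- matrix(0, n, n)
  D[1:5, 6:10] <- 1
  D[6:10, 1:5] <- -1
  D[1:5, 1:5] <- 0.5
  D[6:10, 6:10] <- -0.5
  diag(D) <- 0
  med <- node_median_profile(D)
  expect_true(all(med[1:5] > 0))
  expect_true(all(med[6:10] < 0))
})

test_that("without normalization a global density difference floods the test", {
  # groups differ in overall density; the normalized measure should flag
  # no more pairs than the raw communicability lengths
  set.seed(1234)
  subs_h <- lapply(1:6, function(k) {
    random_graph(20, p = 0.45, connected = TRUE, seed = 1000 + k)$adjacency * 1.0
  })
  subs_d <- lapply(1:6, function(k) {
    random_graph(20, p = 0.25, connected = TRUE, seed = 2000 + k)$adjacency * 1.0
  })
  ch <- cohort(c(subs_h, subs_d), groups = rep(c("group_H", "group_D"), each = 6))
  mc <- build_group_mask(ch, 0)
  pr_raw <- permutation_test(mc, measure = "communicability", n_perm = 200L,
                             seed = 3L)
  pr_hat <- permutation_test(mc, measure = "normalized_communicability",
                             n_perm = 200L, seed = 3L)
  up <- upper.tri(pr_raw$p_values)
  expect_gte(sum(pr_raw$significant_fdr[up], na.rm = TRUE),
             sum(pr_hat$significant_fdr[up], na.rm = TRUE))
})
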