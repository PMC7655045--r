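test_that("si_parameters validates and derives alpha", {
  p <- si_parameters(1, beta = 0.01, n = 5)
  expect_equal(p$x0, rep(0.01, 5))
  expect_equal(p$alpha, 0.99)
  expect_error(si_parameters(0, beta = 0.1, n = 2), "positive")
  expect_error(si_parameters(1, beta = 1, n = 2), "\\[0, 1\\)")
  expect_error(si_parameters(1, x0 = c(0.5, 1.2)), "\\[0, 1\\)")
  expect_true(is.na(si_parameters(1, x0 = c(0.1, 0.2))$beta))
})

test_that("exact SI: edgeless stays put, t=0 returns x0, complete graph is logistic", {
  p <- si_parameters(0.5, beta = 0.1, n = 4)
  tr <- integrate_exact_si(net_edgeless(4), p, c(0, 1, 5))
  expect_equal(unname(tr$states), matrix(0.1, 3, 4), tolerance = 1e-10)

  n <- 6
  kn <- comm_network(matrix(1, n, n) - diag(n))
  p <- si_parameters(0.3, beta = 0.05, n = n)
  times <- seq(0, 4, length.out = 9)
  tr <- integrate_exact_si(kn, p, times)
  expect_equal(unname(tr$states[1, ]), rep(0.05, n))
  # symmetry reduces K_n to the scalar logistic x' = gamma(1-x)(n-1)x
  x0 <- 0.05
  g <- 0.3 * (n - 1)
  logistic <- x0 * exp(g * times) / (1 - x0 + x0 * exp(g * times))
  for (k in seq_along(times)) {
    expect_equal(unname(tr$states[k, ]), rep(logistic[k], n), tolerance = 1e-6)
  }
})

test_that("exact trajectories are monotone and within [0, 1]", {
  for (seed in 1:5) {
    net <- random_connected_net(sample(5:12, 1), p = 0.4, seed = 600 + seed)
    p <- si_parameters(0.4, beta = 0.02, n = n_nodes(net))
    tr <- integrate_exact_si(net, p, seq(0, 8, length.out = 20))
    expect_true(all(tr$states >= 0 & tr$states <= 1))
    expect_true(all(diff(tr$states) >= -1e-8))
  }
})

test_that("linearized solution matches the spectral closed form", {
  p <- si_parameters(0.7, beta = 0.01, n = 2)
  # K2: each entry beta * e^(gamma t) via cosh + sinh
  for (t in c(0, 0.5, 2)) {
    x <- linearized_si(net_k2(), p, t)
    expect_equal(unname(x), rep(0.01 * exp(0.7 * t), 2), tolerance = 1e-12)
  }
  expect_equal(unname(linearized_si(net_edgeless(3),
                                    si_parameters(1, beta = 0.2, n = 3), 7)),
               rep(0.2, 3))
  # divergence is expected, not clipped
  expect_gt(max(linearized_si(net_k2(), p, 20)), 1)
})

test_that("surrogate starts at beta, stays bounded, is constant on edgeless graphs", {
  p <- si_parameters(0.5, beta = 0.03, n = 5)
  net <- random_connected_net(5, seed = 61)
  expect_equal(unname(surrogate_si(net, p, 0)), rep(0.03, 5), tolerance = 1e-12)
  for (t in c(0.5, 2, 10)) {
    x <- surrogate_si(net, p, t)
    # mathematically x < 1 for finite t; doubles saturate to exactly 1
    expect_true(all(x >= 0 & x <= 1))
  }
  expect_equal(unname(surrogate_si(net_edgeless(5), p, 50)), rep(0.03, 5),
               tolerance = 1e-12)
  expect_error(surrogate_si(net, si_parameters(1, x0 = c(0.1, 0.2, 0.1, 0.1, 0.1)), 1),
               "uniform")
})

test_that("exact <= surrogate <= linearized entrywise along trajectories", {
  for (seed in 1:6) {
    net <- random_connected_net(sample(6:15, 1), p = 0.35, seed = 700 + seed)
    n <- n_nodes(net)
    p <- si_parameters(0.3, beta = 2 / n, n = n)
    times <- seq(0, 6, length.out = 12)
    exact <- integrate_exact_si(net, p, times)$states
    for (k in seq_along(times)) {
      surr <- surrogate_si(net, p, times[k])
      lin <- linearized_si(net, p, times[k])
      expect_true(all(exact[k, ] <= surr + 1e-7))
      expect_true(all(surr <= pmin(1, lin) + 1e-10))
    }
  }
})

test_that("surrogate trajectories are monotone and saturate on connected graphs", {
  net <- random_connected_net(10, seed = 55)
  p <- si_parameters(0.5, beta = 0.01, n = 10)
  tr <- surrogate_si_trajectory(net, p, seq(0, 40, length.out = 30))
  expect_true(all(diff(tr$states) >= -1e-12))
  expect_true(all(tr$states[30, ] > 0.999))
})

test_that("infection time is Inf when unreachable and 0 when already crossed", {
  p <- si_parameters(1, beta = 0.05, n = 4)
  expect_identical(infection_time(net_edgeless(4), p), Inf)
  expect_equal(infection_time(net_k2(), si_parameters(1, beta = 0.995, n = 2),
                              theta = 0.99), 0)
  expect_error(infection_time(net_k2(), si_parameters(1, beta = 0.1, n = 2),
                              theta = 1.5), "\\(0, 1\\)")
})

test_that("adding an edge never slows infection; denser graphs infect faster", {
  p3 <- si_parameters(0.5, beta = 1 / 3, n = 3)
  expect_lte(infection_time(net_k3(), p3), infection_time(net_p3(), p3))
  for (seed in 1:20) {
    net <- random_connected_net(sample(5:9, 1), p = 0.4, seed = 800 + seed)
    n <- n_nodes(net)
    p <- si_parameters(0.5, beta = 1 / n, n = n)
    A <- net$adjacency
    missing_pairs <- which(upper.tri(A) & A == 0, arr.ind = TRUE)
    if (nrow(missing_pairs) == 0) next
    pick <- missing_pairs[((seed - 1L) %% nrow(missing_pairs)) + 1L, ]
    A2 <- A
    A2[pick[1], pick[2]] <- A2[pick[2], pick[1]] <- 1L
    t0 <- infection_time(net, p)
    t1 <- infection_time(comm_network(A2), p)
    expect_lte(t1, t0 + 1e-9)
  }
})
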