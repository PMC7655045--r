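#' SI model parameters
#'
#' Parameter bundle for susceptible-infected propagation: infection rate
#' `gamma` (per unit time) and per-node initial infection probabilities.
#' The uniform start `x0 = beta = c/n` is the regime under which the
#' surrogate solution is derived; `alpha = 1 - beta`.
#'
#' @param gamma positive infection rate.
#' @param beta uniform initial infection probability in `[0, 1)`; ignored
#'   when `x0` is given.
#' @param x0 optional explicit vector of initial probabilities in `[0, 1)`.
#' @param n number of nodes (needed when only `beta` is given).
#' @return An `si_parameters` object with `gamma`, `x0`, `beta` (`NA` when
#'   the start is non-uniform) and `alpha`.
#' @export
si_parameters <- function(gamma, beta = NULL, x0 = NULL, n = NULL) {
  if (!is.numeric(gamma) || length(gamma) != 1L || gamma <= 0) {
    stop("gamma must be a single positive number")
  }
  if (is.null(x0)) {
    if (is.null(beta) || is.null(n)) stop("give either x0 or both beta and n")
    if (beta < 0 || beta >= 1) stop("beta must be in [0, 1)")
    x0 <- rep(beta, n)
  } else {
    if (any(x0 < 0 | x0 >= 1)) stop("initial probabilities must lie in [0, 1)")
    beta <- if (length(unique(x0)) == 1L) x0[1L] else NA_real_
  }
  structure(list(gamma = gamma, x0 = as.numeric(x0), beta = beta,
                 alpha = 1 - beta),
            class = "si_parameters")
}

#' Exact SI trajectories
#'
#' Numerically integrates the coupled susceptible-infected equations
#' `dx_i/dt = gamma * (1 - x_i) * sum_j A_ij x_j` with an adaptive
#' stiff-capable solver (`deSolve::ode`, lsoda, rtol 1e-8, atol 1e-10).
#' States are clipped to `[0, 1]` within tolerance.
#'
#' @param net a [comm_network()].
#' @param p an [si_parameters()] object with `length(x0) == n_nodes(net)`.
#' @param times increasing vector of time points starting at 0.
#' @return An `si_trajectory` object: `times`, `states` (length(times) x n
#'   matrix of probabilities) and `variant = "exact"`.
#' @export
integrate_exact_si <- function(net, p, times) {
  stopifnot(inherits(net, "comm_network"), inherits(p, "si_parameters"))
  n <- n_nodes(net)
  if (length(p$x0) != n) stop("x0 length does not match network size")
  if (length(times) < 1L || times[1L] != 0 || is.unsorted(times, strictly = TRUE)) {
    stop("times must increase strictly from 0")
  }
  A <- net$adjacency
  gamma <- p$gamma
  rhs <- function(t, x, parms) list(gamma * (1 - x) * as.vector(A %*% x))
  sol <- deSolve::ode(y = p$x0, times = times, func = rhs, parms = NULL,
                      rtol = 1e-8, atol = 1e-10)
  if (attr(sol, "istate")[1L] < 0) stop("SI integration failed: ", paste(
    utils::capture.output(deSolve::diagnostics(sol)), collapse = "\n"))
  states <- unname(sol[, -1L, drop = FALSE])
  states <- pmin(pmax(states, 0), 1)
  si_trajectory(times, states, "exact", net$labels)
}

#' Linearized SI solution
#'
#' The solution `x*(t) = expm(gamma * t * A) %*% x0` of the linearized
#' equations `dx/dt = gamma * A x`, computed spectrally. It upper-bounds the
#' exact solution but is unbounded: entries exceed 1 and diverge as `t`
#' grows; no clipping is applied, since divergence is the expected behavior
#' of the linear semigroup.
#'
#' @inheritParams integrate_exact_si
#' @param t single nonnegative time.
#' @return Numeric length-n vector (not restricted to `[0, 1]`).
#' @export
linearized_si <- function(net, p, t) {
  stopifnot(inherits(net, "comm_network"), inherits(p, "si_parameters"))
  if (length(t) != 1L || t < 0) stop("t must be a single nonnegative time")
  if (length(p$x0) != n_nodes(net)) stop("x0 length does not match network size")
  eig <- eigen(net$adjacency, symmetric = TRUE)
  out <- eig$vectors %*% (exp(p$gamma * t * eig$values) * crossprod(eig$vectors, p$x0))
  stats::setNames(as.vector(out), net$labels)
}

#' Bounded surrogate SI solution
#'
#' The log-transform surrogate: with `y_i = -log(1 - x_i)` the exact SI
#' system becomes `dy/dt = gamma * A (1 - exp(-y))`; bounding the concave
#' map `y -> 1 - exp(-y)` by its tangent line at the uniform start
#' `y(0) = -log(alpha)` gives the linear system whose closed-form solution
#' is
#' \deqn{y(t) = (\beta/\alpha)\, e^{\alpha\gamma t A} \mathbf{1}
#'       - (\log\alpha + \beta/\alpha) \mathbf{1},}
#' and the surrogate state `x~ = 1 - exp(-y)`, which stays in `[0, 1)`,
#' is nondecreasing in `t`, starts exactly at `beta` and tightly
#' upper-bounds the exact solution. Requires the uniform start
#' `x0_i = beta` for all `i` (the tangent point is common to all nodes).
#'
#' @inheritParams linearized_si
#' @return Numeric length-n vector in `[0, 1)`.
#' @export
surrogate_si <- function(net, p, t) {
  stopifnot(inherits(net, "comm_network"), inherits(p, "si_parameters"))
  if (length(t) != 1L || t < 0) stop("t must be a single nonnegative time")
  y <- surrogate_y(net, p, t)
  stats::setNames(1 - exp(-y), net$labels)
}

# y(t) of the surrogate, shared by surrogate_si() and infection_time()
surrogate_y <- function(net, p, t, eig = NULL) {
  if (is.na(p$beta)) {
    stop("the surrogate solution requires a uniform initial condition x0_i = beta")
  }
  if (length(p$x0) != n_nodes(net)) stop("x0 length does not match network size")
  alpha <- p$alpha
  beta <- p$beta
  if (beta == 0) return(rep(0, n_nodes(net)))  # nothing to propagate
  if (is.null(eig)) eig <- eigen(net$adjacency, symmetric = TRUE)
  ones <- rep(1, n_nodes(net))
  e1 <- eig$vectors %*% (exp(alpha * p$gamma * t * eig$values) * crossprod(eig$vectors, ones))
  y <- (beta / alpha) * as.vector(e1) - (log(alpha) + beta / alpha)
  # the tangent construction guarantees y(0) = -log(alpha); self-check
  if (t == 0 && max(abs(y + log(alpha))) > 1e-8) {
    stop("surrogate self-check failed: y(0) != -log(alpha)")
  }
  y
}

#' Surrogate trajectories on a time grid
#'
#' Convenience wrapper evaluating [surrogate_si()] on a vector of times.
#'
#' @inheritParams integrate_exact_si
#' @return An `si_trajectory` with `variant = "surrogate"`.
#' @export
surrogate_si_trajectory <- function(net, p, times) {
  states <- t(vapply(times, function(t) surrogate_si(net, p, t),
                     numeric(n_nodes(net))))
  si_trajectory(times, states, "surrogate", net$labels)
}

si_trajectory <- function(times, states, variant, labels) {
  colnames(states) <- labels
  structure(list(times = times, states = states, variant = variant),
            class = "si_trajectory")
}

#' @export
print.si_trajectory <- function(x, ...) {
  cat("<si_trajectory> variant = ", x$variant, ", ", length(x$times),
      " times, ", ncol(x$states), " nodes\n", sep = "")
  invisible(x)
}

#' Time to full infection under the surrogate dynamics
#'
#' Smallest `t` at which every node's surrogate infection probability
#' reaches `theta`, found by root bracketing and bisection on the monotone
#' surrogate (`stats::uniroot`). Returns `Inf` when some node can never
#' reach `theta` (isolated nodes keep `x~ = beta` forever).
#'
#' The crossing level `theta` defaults to 0.99; "all nodes infected" has no
#' canonical probability cutoff, and percentage *changes* of the infection
#' time under perturbation are insensitive to it, so it is surfaced as an
#' argument rather than fixed.
#'
#' @inheritParams integrate_exact_si
#' @param theta crossing threshold in `(0, 1)`.
#' @return Nonnegative scalar time, or `Inf`.
#' @export
infection_time <- function(net, p, theta = 0.99) {
  stopifnot(inherits(net, "comm_network"), inherits(p, "si_parameters"))
  if (!is.numeric(theta) || length(theta) != 1L || theta <= 0 || theta >= 1) {
    stop("theta must be in (0, 1)")
  }
  if (is.na(p$beta)) stop("infection_time uses the surrogate, which needs a uniform start")
  if (p$beta >= theta) return(0)
  # an isolated node keeps y = -log(alpha): unreachable threshold
  if (p$beta == 0 || any(rowSums(net$adjacency) == 0)) return(Inf)
  eig <- eigen(net$adjacency, symmetric = TRUE)
  target <- -log(1 - theta)
  f <- function(t) min(surrogate_y(net, p, t, eig = eig)) - target
  hi <- 1
  while (f(hi) < 0) {
    hi <- hi * 2
    if (hi > 1e12) return(Inf)  # pathological: growth too slow to matter
  }
  stats::uniroot(f, c(0, hi), tol = 1e-10)$root
}
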