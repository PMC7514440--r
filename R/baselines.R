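# Reference MCMC samplers: Metropolis-adjusted Langevin (MALA) and
# Hamiltonian Monte Carlo with leapfrog integration.

#' Metropolis-adjusted Langevin chain
#'
#' Proposes `x' = x - (eps^2/2) gradU(x) + eps z`, `z ~ N(0, I)`, and accepts
#' with the Metropolis-Hastings ratio using the asymmetric Gaussian proposal
#' density both ways. Burn-in draws are discarded from the returned chain.
#'
#' @param target a [target_distribution()].
#' @param n_iterations total iterations.
#' @param step_size positive Langevin step size eps.
#' @param burn_in iterations to discard (< n_iterations).
#' @param init_position starting point (default origin).
#' @param seed optional integer seed.
#' @return list with `chain` ((n_iterations - burn_in) x D matrix) and
#'   `acceptance_rate`.
#' @export
mala_chain <- function(target, n_iterations = 10000L, step_size = 0.1,
                       burn_in = 0L, init_position = NULL, seed = NULL) {
  stopifnot(inherits(target, "target_distribution"))
  if (step_size <= 0) stop("step_size must be positive")
  if (burn_in >= n_iterations) stop("burn_in must be smaller than n_iterations")
  if (!is.null(seed)) set.seed(seed)
  D <- target$dim
  x <- if (is.null(init_position)) rep(0, D) else as.numeric(init_position)
  eps <- step_size
  a <- eps^2 / 2
  u1 <- function(p) tgt_energy(target, matrix(p, 1L))[[1L]]
  g1 <- function(p) drop(tgt_grad(target, matrix(p, 1L)))
  lq <- function(to, from, gfrom) -sum((to - from + a * gfrom)^2) / (2 * eps^2)
  Ux <- u1(x); gx <- g1(x)
  keep <- n_iterations - burn_in
  chain <- matrix(NA_real_, keep, D)
  acc <- 0L
  for (it in seq_len(n_iterations)) {
    z <- stats::rnorm(D)
    xp <- x - a * gx + eps * z
    Up <- u1(xp); gp <- g1(xp)
    log_alpha <- (Ux - Up) + lq(x, xp, gp) - lq(xp, x, gx)
    if (is.finite(log_alpha) && log(stats::runif(1L)) < log_alpha) {
      x <- xp; Ux <- Up; gx <- gp
      acc <- acc + 1L
    }
    if (it > burn_in) chain[it - burn_in, ] <- x
  }
  list(chain = chain, acceptance_rate = acc / n_iterations)
}

#' Hamiltonian Monte Carlo chain
#'
#' Standard leapfrog integrator with unit mass matrix; the number of leapfrog
#' steps is drawn uniformly from `leapfrog_range` at every iteration and the
#' momentum is refreshed each iteration. Proposals are accepted on the total
#' energy change; non-finite energies during integration reject the proposal
#' and are counted.
#'
#' @inheritParams mala_chain
#' @param step_size leapfrog step size.
#' @param leapfrog_range integer range `c(lo, hi)` of leapfrog step counts
#'   per iteration.
#' @return list with `chain`, `acceptance_rate`, and `n_divergent` (count of
#'   non-finite trajectories).
#' @export
hmc_chain <- function(target, n_iterations = 10000L, step_size = 0.1,
                      leapfrog_range = c(80L, 120L), burn_in = 0L,
                      init_position = NULL, seed = NULL) {
  stopifnot(inherits(target, "target_distribution"))
  if (step_size <= 0) stop("step_size must be positive")
  if (burn_in >= n_iterations) stop("burn_in must be smaller than n_iterations")
  lo <- as.integer(leapfrog_range[1L]); hi <- as.integer(leapfrog_range[2L])
  if (lo < 1L || hi < lo) stop("invalid leapfrog_range")
  if (!is.null(seed)) set.seed(seed)
  D <- target$dim
  x <- if (is.null(init_position)) rep(0, D) else as.numeric(init_position)
  u1 <- function(p) tgt_energy(target, matrix(p, 1L))[[1L]]
  g1 <- function(p) drop(tgt_grad(target, matrix(p, 1L)))
  Ux <- u1(x)
  keep <- n_iterations - burn_in
  chain <- matrix(NA_real_, keep, D)
  acc <- 0L; ndiv <- 0L
  for (it in seq_len(n_iterations)) {
    L <- if (hi > lo) sample(lo:hi, 1L) else lo
    p <- stats::rnorm(D)
    H0 <- Ux + sum(p^2) / 2
    xp <- x
    ok <- TRUE
    p <- p - step_size / 2 * g1(xp)
    for (l in seq_len(L)) {
      xp <- xp + step_size * p
      gl <- g1(xp)
      if (any(!is.finite(gl)) || !is.finite(u1(xp))) { ok <- FALSE; break }
      p <- p - step_size * (if (l < L) gl else gl / 2)
    }
    if (ok) {
      Up <- u1(xp)
      H1 <- Up + sum(p^2) / 2
      if (is.finite(H1) && log(stats::runif(1L)) < H0 - H1) {
        x <- xp; Ux <- Up
        acc <- acc + 1L
      }
    } else {
      ndiv <- ndiv + 1L
    }
    if (it > burn_in) chain[it - burn_in, ] <- x
  }
  list(chain = chain, acceptance_rate = acc / n_iterations,
       n_divergent = ndiv)
}

# single leapfrog trajectory (used by integrator tests): returns the end
# state of L steps of size eps from (x, p)
leapfrog <- function(target, x, p, step_size, L) {
  g1 <- function(q) drop(tgt_grad(target, matrix(q, 1L)))
  p <- p - step_size / 2 * g1(x)
  for (l in seq_len(L)) {
    x <- x + step_size * p
    p <- p - step_size * (if (l < L) g1(x) else g1(x) / 2)
  }
  list(x = x, p = p)
}
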