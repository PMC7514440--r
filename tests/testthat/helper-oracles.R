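# Shared oracles and fixtures, built in code.

# central-difference gradient of a target's energy (independent of the
# target's own grad_energy)
fd_grad <- function(tg, x, h = 1e-6) {
  vapply(seq_along(x), function(j) {
    e <- numeric(length(x)); e[j] <- h
    (energy(tg, x + e) - energy(tg, x - e)) / (2 * h)
  }, numeric(1))
}

# central-difference diagonal Hessian from the target's gradient
fd_diag_hess <- function(tg, x, h = 1e-5) {
  vapply(seq_along(x), function(j) {
    e <- numeric(length(x)); e[j] <- h
    (grad_energy(tg, x + e)[j] - grad_energy(tg, x - e)[j]) / (2 * h)
  }, numeric(1))
}

# a tiny stack with parameters perturbed away from the pure-Langevin init,
# so conditioners are active in property tests
tiny_stack <- function(target, epsilon, langevin_steps = 2L, n_layers = 2L,
                       hidden = c(4L), sd = 0.05, seed = 42L,
                       base_mean = NULL, base_scale = NULL) {
  st <- flow_stack(target, n_layers = n_layers, epsilon = epsilon,
                   langevin_steps = langevin_steps, hidden = hidden,
                   base_mean = base_mean, base_scale = base_scale, seed = seed)
  skel <- nflmc:::stack_params(st)
  th <- nflmc:::tree_flatten(skel)
  set.seed(seed + 1L)
  th <- th + stats::rnorm(length(th), 0, sd)
  nflmc:::stack_set_params(st, nflmc:::tree_unflatten(skel, th))
}

# 2-D grid quadrature of exp(log_density) over [lo1,hi1] x [lo2,hi2]
quad2d_mass <- function(log_density_fn, lims, n_grid = 160L) {
  g1 <- seq(lims[1L], lims[2L], length.out = n_grid)
  g2 <- seq(lims[3L], lims[4L], length.out = n_grid)
  d1 <- g1[2L] - g1[1L]; d2 <- g2[2L] - g2[1L]
  G <- as.matrix(expand.grid(g1, g2))
  sum(exp(log_density_fn(G))) * d1 * d2
}
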