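# Langevin coupling layers: forward transform, approximate inverse via the
# one-step surrogate, diagonal log-Jacobians, and the stacked flow with a
# diagonal-Gaussian base distribution.
#
# Each layer updates the two coordinate blocks in turn. A block update applies
# Ls deterministic Langevin half-steps
#     x_u <- x_u - (eps^2/2) * gradU(x)_u + eps * exp(sigma(x_c))
# the last of which is fused with an affine rescale
#     y_u = (x_u - (eps^2/2) gradU(x)_u + eps e^{sigma(x_c)}) * e^{S(x_c)} + T(x_c),
# where sigma, S, T are conditioner networks reading the complementary block.
# The Jacobian of each update is triangular; its diagonal carries
# (1 - (eps^2/2) H_ii) e^{S_i} for the fused step and (1 - (eps^2/2) H_ii) for
# pure steps, H being the diagonal of the target Hessian at the pre-update
# point. The inverse replaces the unknown pre-image inside gradU by the
# gradient-free surrogate (t1/t2 trick), which is exact at eps = 0 and has
# O(eps^2) error otherwise.

#' Diagonal-Gaussian base distribution
#'
#' @param mean mean vector.
#' @param scale positive standard deviations (recycled to length of mean).
#' @return an object of class `"base_distribution"`.
#' @export
base_distribution <- function(mean, scale = 1) {
  mean <- as.numeric(mean)
  scale <- rep_len(as.numeric(scale), length(mean))
  if (any(scale <= 0)) stop("base scale must be positive")
  structure(list(mean = mean, scale = scale, dim = length(mean)),
            class = "base_distribution")
}

base_log_density <- function(base, X) {
  X <- as_points(X, base$dim)
  out <- numeric(nrow(X))
  for (j in seq_len(base$dim))
    out <- out + stats::dnorm(X[, j], base$mean[j], base$scale[j], log = TRUE)
  out
}

base_sample <- function(base, n) {
  D <- base$dim
  Z <- matrix(stats::rnorm(n * D), n, D)
  sweep(Z * rep(base$scale, each = n), 2L, base$mean, "+")
}

# Scale conditioners (sigma and S) are clamped smoothly to +/- COND_BOUND via
# B * tanh(raw / B): unbounded log-scales make exp() overflow reachable within
# a few optimizer steps on heavy-tailed batches. T (the shift) stays linear.
COND_BOUND <- 4

sbound <- function(A) COND_BOUND * tanh(A / COND_BOUND)
# derivative of sbound w.r.t. its input, expressed through the bounded output
sbound_deriv <- function(bounded) 1 - (bounded / COND_BOUND)^2

# ---- layer and stack construction -----------------------------------------

new_coupling_layer <- function(dim, split_index, epsilon, langevin_steps,
                               hidden, flip = FALSE) {
  d <- split_index
  ia <- seq_len(d)            # block conditioning the first update
  ib <- seq.int(d + 1L, dim)  # block updated first
  if (flip) { tmp <- ia; ia <- ib; ib <- tmp }
  make_cond <- function(din, dout)
    list(sigma = mlp_init(din, dout, hidden),
         S = mlp_init(din, dout, hidden),
         T = mlp_init(din, dout, hidden))
  structure(list(
    epsilon = epsilon, langevin_steps = as.integer(langevin_steps),
    ia = ia, ib = ib,
    cond_b = make_cond(length(ia), length(ib)),  # conditions on ia, updates ib
    cond_a = make_cond(length(ib), length(ia))   # conditions on ib, updates ia
  ), class = "coupling_layer")
}

#' Build a Langevin coupling-flow stack
#'
#' Composes `n_layers` coupling layers over a diagonal-Gaussian base. The
#' split index is `floor(D/2)` and the block updated first alternates across
#' consecutive layers. Conditioner networks have ReLU hidden layers of sizes
#' `hidden` and zero-initialized final layers, so a fresh stack is the pure
#' Langevin map (exactly the identity when `epsilon = 0`).
#'
#' @param target a [target_distribution()] (supplies the drift and curvature).
#' @param n_layers number of coupling layers.
#' @param epsilon Langevin step size (>= 0; 0 gives the plain affine-coupling
#'   flow, the "NNFMC" ablation).
#' @param langevin_steps Ls >= 1 half-updates per block, the last fused with
#'   the affine rescale.
#' @param hidden integer vector of conditioner hidden-layer widths.
#' @param base_mean,base_scale base distribution parameters (default standard
#'   normal of the target's dimension).
#' @param seed optional integer seed for parameter initialization.
#' @return an object of class `"flow_stack"`.
#' @export
flow_stack <- function(target, n_layers = 4L, epsilon = 0.05,
                       langevin_steps = 2L, hidden = c(64L, 64L),
                       base_mean = NULL, base_scale = NULL, seed = NULL) {
  stopifnot(inherits(target, "target_distribution"))
  D <- target$dim
  if (D < 2L) stop("coupling layers need D >= 2 (two coordinate blocks)")
  if (epsilon < 0) stop("epsilon must be nonnegative")
  if (langevin_steps < 1L) stop("langevin_steps must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(base_mean)) base_mean <- rep(0, D)
  if (is.null(base_scale)) base_scale <- rep(1, D)
  base <- base_distribution(base_mean, base_scale)
  if (base$dim != D) stop("base dimension must match the target")
  d <- D %/% 2L
  layers <- lapply(seq_len(n_layers), function(t)
    new_coupling_layer(D, d, epsilon, langevin_steps, hidden,
                       flip = (t %% 2L == 0L)))
  structure(list(layers = layers, base = base, target = target,
                 epsilon = epsilon, langevin_steps = as.integer(langevin_steps),
                 hidden = as.integer(hidden), split_index = d),
            class = "flow_stack")
}

#' @export
print.flow_stack <- function(x, ...) {
  cat("Langevin coupling flow: ", length(x$layers), " layers, eps = ",
      format(x$epsilon), ", Ls = ", x$langevin_steps,
      ", conditioners ", paste(x$hidden, collapse = "x"),
      ", target '", x$target$name, "' (D = ", x$target$dim, ")\n", sep = "")
  invisible(x)
}

# ---- forward ---------------------------------------------------------------

# One block-update phase: Ls-1 pure Langevin half-steps then the fused
# Langevin + affine step on block u, conditioned on block c.
phase_forward <- function(X, eps, ls, u, c, cond, target, keep = FALSE) {
  n <- nrow(X)
  a <- eps^2 / 2
  A <- X[, c, drop = FALSE]
  sig <- mlp_forward(cond$sigma, A, keep = keep)
  Sc  <- mlp_forward(cond$S, A, keep = keep)
  Tc  <- mlp_forward(cond$T, A, keep = keep)
  sig_out <- sbound(if (keep) sig$out else sig)
  S_out <- sbound(if (keep) Sc$out else Sc)
  T_out <- if (keep) Tc$out else Tc
  es <- exp(sig_out)
  eS <- exp(S_out)
  logdet <- numeric(n)
  steps <- if (keep) vector("list", ls) else NULL
  for (k in seq_len(ls)) {
    fused <- (k == ls)
    if (eps > 0) {
      gh <- tgt_grad_dhess(target, X)
      G <- gh$G[, u, drop = FALSE]
      H <- gh$H[, u, drop = FALSE]
      jac <- 1 - a * H
      if (any(!is.finite(jac)))
        stop("non-finite target curvature encountered in forward pass ",
             "(points may have left the target's domain)")
      if (any(abs(jac) < 1e-12))
        stop("singular diagonal Jacobian factor |1 - (eps^2/2) H_ii| < 1e-12; ",
             "use a smaller epsilon")
      logdet <- logdet + rowSums(log(abs(jac)))
      inner <- X[, u, drop = FALSE] - a * G + eps * es
    } else {
      H <- NULL
      inner <- X[, u, drop = FALSE]
    }
    if (keep) steps[[k]] <- list(Xpre = X, H = H,
                                 inner = if (fused) inner else NULL)
    if (fused) {
      X[, u] <- inner * eS + T_out
      logdet <- logdet + rowSums(S_out)
    } else {
      X[, u] <- inner
    }
  }
  cache <- if (keep) list(sig = sig, S = Sc, T = Tc, es = es, eS = eS,
                          sigb = sig_out, Sb = S_out, steps = steps) else NULL
  list(X = X, logdet = logdet, cache = cache)
}

#' Apply one coupling layer forward
#'
#' Updates the layer's first block (Ls Langevin half-steps, the last fused with
#' the affine rescale), then the second block conditioned on the updated first.
#' Returns the transformed points and the accumulated forward log-Jacobian
#' (diagonal approximation: exact whenever the target Hessian is diagonal).
#'
#' @param x point (length-D vector) or n x D matrix.
#' @param layer a coupling layer from a [flow_stack()].
#' @param target the [target_distribution()] supplying gradients/curvature.
#' @return list with `z` (same shape as `x`) and `fwd_logdet`.
#' @export
forward_layer <- function(x, layer, target) {
  X <- as_points(x, target$dim)
  p1 <- phase_forward(X, layer$epsilon, layer$langevin_steps,
                      layer$ib, layer$ia, layer$cond_b, target)
  p2 <- phase_forward(p1$X, layer$epsilon, layer$langevin_steps,
                      layer$ia, layer$ib, layer$cond_a, target)
  z <- if (is.null(dim(x))) drop(p2$X) else p2$X
  list(z = z, fwd_logdet = p1$logdet + p2$logdet)
}

layer_forward_cached <- function(X, layer, target) {
  p1 <- phase_forward(X, layer$epsilon, layer$langevin_steps,
                      layer$ib, layer$ia, layer$cond_b, target, keep = TRUE)
  p2 <- phase_forward(p1$X, layer$epsilon, layer$langevin_steps,
                      layer$ia, layer$ib, layer$cond_a, target, keep = TRUE)
  list(X = p2$X, logdet = p1$logdet + p2$logdet,
       cache = list(p1 = p1$cache, p2 = p2$cache))
}

#' One deterministic Langevin half-step
#'
#' Updates the named block only: `new = block - (eps^2/2) gradU(x)_block +
#' eps * exp(sigma(other))`, leaving the complementary block unchanged. The
#' "noise" is the learned term `eps * exp(sigma(.))`, not a random draw.
#' `"first"`/`"second"` name the block in the layer's own update order (the
#' layer updates `"first"` before `"second"`).
#'
#' @inheritParams forward_layer
#' @param block which block to update.
#' @return the updated point, same shape as `x`.
#' @export
langevin_half_step <- function(x, block = c("first", "second"), layer, target) {
  block <- match.arg(block)
  X <- as_points(x, target$dim)
  if (block == "first") { u <- layer$ib; c <- layer$ia; cond <- layer$cond_b }
  else { u <- layer$ia; c <- layer$ib; cond <- layer$cond_a }
  eps <- layer$epsilon
  sig <- sbound(mlp_forward(cond$sigma, X[, c, drop = FALSE]))
  upd <- X[, u, drop = FALSE] + eps * exp(sig)
  if (eps > 0) {
    G <- tgt_grad(target, X)[, u, drop = FALSE]
    if (any(!is.finite(G))) {
      bad <- which(!is.finite(G), arr.ind = TRUE)
      stop("non-finite target gradient at updated coordinate(s) ",
           paste(unique(u[bad[, 2L]]), collapse = ", "))
    }
    upd <- upd - (eps^2 / 2) * G
  }
  X[, u] <- upd
  if (is.null(dim(x))) drop(X) else X
}

# ---- inverse ---------------------------------------------------------------

# Invert one phase: given the updated block z_u and the (unchanged)
# conditioning block c, recover the pre-update block. The fused step uses the
# gradient-free surrogate t = (z_u - T) e^{-S} - eps e^{sigma}, then one
# corrected update x_u = t + (eps^2/2) gradU(t, c)_u; pure steps the same with
# S = 0, T = 0. Inverse log-Jacobians accumulate -S_i + log|1 + (eps^2/2) H_ii|
# (fused) and log|1 + (eps^2/2) H_ii| (pure), H evaluated at the surrogate.
phase_inverse <- function(X, eps, ls, u, c, cond, target) {
  n <- nrow(X)
  a <- eps^2 / 2
  A <- X[, c, drop = FALSE]
  es <- exp(sbound(mlp_forward(cond$sigma, A)))
  S_out <- sbound(mlp_forward(cond$S, A))
  T_out <- mlp_forward(cond$T, A)
  logdet <- numeric(n)
  for (k in rev(seq_len(ls))) {
    fused <- (k == ls)
    if (fused) {
      t_sur <- (X[, u, drop = FALSE] - T_out) * exp(-S_out) - eps * es
      logdet <- logdet - rowSums(S_out)
    } else {
      t_sur <- X[, u, drop = FALSE] - eps * es
    }
    if (eps > 0) {
      M <- X
      M[, u] <- t_sur
      gh <- tgt_grad_dhess(target, M)
      G <- gh$G[, u, drop = FALSE]
      H <- gh$H[, u, drop = FALSE]
      jac <- 1 + a * H
      if (any(abs(jac) < 1e-12))
        stop("singular diagonal Jacobian factor |1 + (eps^2/2) H_ii| < 1e-12; ",
             "use a smaller epsilon")
      logdet <- logdet + rowSums(log(abs(jac)))
      X[, u] <- t_sur + a * G
    } else {
      X[, u] <- t_sur
    }
  }
  list(X = X, logdet = logdet)
}

#' Apply one coupling layer in reverse
#'
#' Approximate inverse of [forward_layer()] using the one-step surrogate for
#' the Langevin drift (exact at `epsilon = 0`; error O(eps^2) otherwise),
#' with the inverse diagonal log-Jacobian accumulated per coordinate.
#'
#' @inheritParams forward_layer
#' @param z point or matrix of points in the layer's output space.
#' @return list with `x` (pre-image) and `inv_logdet`.
#' @export
inverse_layer <- function(z, layer, target) {
  Z <- as_points(z, target$dim)
  # undo the second phase (block ia, conditioned on ib), then the first
  p2 <- phase_inverse(Z, layer$epsilon, layer$langevin_steps,
                      layer$ia, layer$ib, layer$cond_a, target)
  p1 <- phase_inverse(p2$X, layer$epsilon, layer$langevin_steps,
                      layer$ib, layer$ia, layer$cond_b, target)
  x <- if (is.null(dim(z))) drop(p1$X) else p1$X
  list(x = x, inv_logdet = p2$logdet + p1$logdet)
}

#' Push points through the whole flow
#'
#' @param stack a [flow_stack()].
#' @param x points (vector or n x D matrix).
#' @return list with `z` and total `fwd_logdet`.
#' @export
flow_forward <- function(stack, x) {
  X <- as_points(x, stack$target$dim)
  logdet <- numeric(nrow(X))
  for (layer in stack$layers) {
    out <- forward_layer(X, layer, stack$target)
    X <- out$z
    logdet <- logdet + out$fwd_logdet
  }
  list(z = if (is.null(dim(x))) drop(X) else X, fwd_logdet = logdet)
}

#' Pull points back through the whole flow
#'
#' @param stack a [flow_stack()].
#' @param z points in the flow's output space.
#' @return list with `x` (pre-image) and total `inv_logdet`.
#' @export
flow_inverse <- function(stack, z) {
  Z <- as_points(z, stack$target$dim)
  logdet <- numeric(nrow(Z))
  for (layer in rev(stack$layers)) {
    out <- inverse_layer(Z, layer, stack$target)
    Z <- out$x
    logdet <- logdet + out$inv_logdet
  }
  list(x = if (is.null(dim(z))) drop(Z) else Z, inv_logdet = logdet)
}

#' Flow log-density at arbitrary points
#'
#' `log pi_u(z) = log pi_q(f^{-1}(z)) + log |det d f^{-1} / dz|`, computed by
#' pulling `z` back through all layers with the approximate inverse.
#'
#' @param stack a [flow_stack()].
#' @param z points (vector or matrix).
#' @return vector of log-densities.
#' @export
flow_log_prob <- function(stack, z) {
  inv <- flow_inverse(stack, z)
  X0 <- as_points(inv$x, stack$target$dim)
  base_log_density(stack$base, X0) + inv$inv_logdet
}

#' Draw samples from the flow
#'
#' Draws `n` base samples, pushes them forward, and records per-draw flow
#' log-densities and unnormalized target log-densities (`-U`). Identical seed
#' and parameters give identical batches.
#'
#' @param stack a [flow_stack()].
#' @param n number of draws.
#' @param seed optional integer seed.
#' @param log_prob `"inverse"` evaluates densities with [flow_log_prob()] (the
#'   approximate-inverse route); `"forward"` uses the exact forward identity
#'   `log q(x0) - fwd_logdet` for the pushed samples.
#' @return an object of class `"sample_batch"`: list with `points`
#'   (n x D matrix), `log_q_flow`, `log_target_unnorm`, and the target's
#'   `log_norm_const` (or `NULL`).
#' @export
sample_flow <- function(stack, n, seed = NULL,
                        log_prob = c("inverse", "forward")) {
  log_prob <- match.arg(log_prob)
  if (n < 1) stop("n must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  X0 <- base_sample(stack$base, n)
  fwd <- flow_forward(stack, X0)
  Z <- as_points(fwd$z, stack$target$dim)
  lq <- if (log_prob == "forward")
    base_log_density(stack$base, X0) - fwd$fwd_logdet
  else flow_log_prob(stack, Z)
  sample_batch(Z, lq, -tgt_energy(stack$target, Z),
               log_norm_const = stack$target$log_norm_const)
}

#' Bundle draws with their log-densities
#'
#' @param points n x D matrix of draws.
#' @param log_q_flow per-draw flow log-density `ln pi_u`.
#' @param log_target_unnorm per-draw unnormalized target log-density `-U`.
#' @param log_norm_const the target's known `ln Z`, or `NULL`.
#' @return an object of class `"sample_batch"`.
#' @export
sample_batch <- function(points, log_q_flow, log_target_unnorm,
                         log_norm_const = NULL) {
  points <- as.matrix(points)
  if (length(log_q_flow) != nrow(points) ||
      length(log_target_unnorm) != nrow(points))
    stop("log-density vectors must match the number of rows in points")
  structure(list(points = points, log_q_flow = as.numeric(log_q_flow),
                 log_target_unnorm = as.numeric(log_target_unnorm),
                 log_norm_const = log_norm_const),
            class = "sample_batch")
}

#' @export
print.sample_batch <- function(x, ...) {
  cat("Sample batch: ", nrow(x$points), " draws in D = ", ncol(x$points),
      "\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.sample_batch <- function(x, ...) {
  df <- as.data.frame(x$points)
  names(df) <- paste0("x", seq_len(ncol(x$points)))
  df$log_q_flow <- x$log_q_flow
  df$log_target_unnorm <- x$log_target_unnorm
  df
}

# ---- backward (reverse-mode) ----------------------------------------------

# Backpropagate through one phase. Ubar: n x D cotangent on the phase output;
# lambda: length-n cotangent on the accumulated forward logdet. Returns the
# cotangent on the phase input and gradients for the three conditioners.
phase_backward <- function(cache, Ubar, lambda, eps, ls, u, c, cond, target) {
  n <- nrow(Ubar); D <- ncol(Ubar)
  a <- eps^2 / 2
  ubar <- Ubar[, u, drop = FALSE]
  cbar <- Ubar[, c, drop = FALSE]
  sigbar <- matrix(0, n, length(u))
  Sbar <- NULL; Tbar <- NULL
  for (k in rev(seq_len(ls))) {
    st <- cache$steps[[k]]
    if (k == ls) {
      Tbar <- ubar
      innerbar <- ubar * cache$eS
      inner0 <- if (is.null(st$inner)) st$Xpre[, u, drop = FALSE] else st$inner
      Sbar <- innerbar * inner0 + lambda
    } else {
      innerbar <- ubar
    }
    sigbar <- sigbar + innerbar * eps * cache$es
    if (eps > 0) {
      Vg <- matrix(0, n, D); Vg[, u] <- -a * innerbar
      Xb <- tgt_hess_vp(target, st$Xpre, Vg)
      Wh <- matrix(0, n, D); Wh[, u] <- -a * lambda / (1 - a * st$H)
      Xb <- Xb + tgt_dhess_vp(target, st$Xpre, Wh)
      ubar <- innerbar + Xb[, u, drop = FALSE]
      cbar <- cbar + Xb[, c, drop = FALSE]
    } else {
      ubar <- innerbar
    }
  }
  bs <- mlp_backward(cond$sigma, cache$sig, sigbar * sbound_deriv(cache$sigb))
  bS <- mlp_backward(cond$S, cache$S, Sbar * sbound_deriv(cache$Sb))
  bT <- mlp_backward(cond$T, cache$T, Tbar)
  cbar <- cbar + bs$Xbar + bS$Xbar + bT$Xbar
  Xbar <- matrix(0, n, D)
  Xbar[, u] <- ubar
  Xbar[, c] <- cbar
  list(Xbar = Xbar,
       grads = list(sigma = list(W = bs$dW, b = bs$db),
                    S = list(W = bS$dW, b = bS$db),
                    T = list(W = bT$dW, b = bT$db)))
}

layer_backward <- function(layer, lcache, Zbar, lambda, target) {
  p2 <- phase_backward(lcache$p2, Zbar, lambda, layer$epsilon,
                       layer$langevin_steps, layer$ia, layer$ib,
                       layer$cond_a, target)
  p1 <- phase_backward(lcache$p1, p2$Xbar, lambda, layer$epsilon,
                       layer$langevin_steps, layer$ib, layer$ia,
                       layer$cond_b, target)
  list(Xbar = p1$Xbar, grads = list(cond_b = p1$grads, cond_a = p2$grads))
}

# ---- inverse-route backward (score-style gradient) -------------------------

# phase_inverse with caches for backprop w.r.t. parameters at fixed z
phase_inverse_cached <- function(X, eps, ls, u, c, cond, target) {
  n <- nrow(X)
  a <- eps^2 / 2
  A <- X[, c, drop = FALSE]
  sig <- mlp_forward(cond$sigma, A, keep = TRUE)
  Sc <- mlp_forward(cond$S, A, keep = TRUE)
  Tc <- mlp_forward(cond$T, A, keep = TRUE)
  sigb <- sbound(sig$out)
  Sb <- sbound(Sc$out)
  es <- exp(sigb)
  emS <- exp(-Sb)
  logdet <- numeric(n)
  steps <- vector("list", ls)
  for (k in rev(seq_len(ls))) {
    fused <- (k == ls)
    xu_in <- X[, u, drop = FALSE]
    if (fused) {
      t_sur <- (xu_in - Tc$out) * emS - eps * es
      logdet <- logdet - rowSums(Sb)
    } else {
      t_sur <- xu_in - eps * es
    }
    if (eps > 0) {
      M <- X
      M[, u] <- t_sur
      gh <- tgt_grad_dhess(target, M)
      H <- gh$H[, u, drop = FALSE]
      jac <- 1 + a * H
      if (any(!is.finite(jac)) || any(abs(jac) < 1e-12))
        stop("degenerate inverse Jacobian factor; use a smaller epsilon")
      logdet <- logdet + rowSums(log(abs(jac)))
      X[, u] <- t_sur + a * gh$G[, u, drop = FALSE]
      steps[[k]] <- list(M = M, H = H)
    } else {
      X[, u] <- t_sur
      steps[[k]] <- list(M = NULL, H = NULL)
    }
    steps[[k]]$xu_in <- xu_in
  }
  list(X = X, logdet = logdet,
       cache = list(sig = sig, S = Sc, T = Tc, sigb = sigb, Sb = Sb,
                    es = es, emS = emS, steps = steps))
}

# cotangent on this phase's output (and lambda on the accumulated inverse
# logdet) -> cotangent on its input + parameter gradients
phase_inverse_backward <- function(cache, Ubar, lambda, eps, ls, u, c, cond,
                                   target) {
  n <- nrow(Ubar); D <- ncol(Ubar)
  a <- eps^2 / 2
  ubar <- Ubar[, u, drop = FALSE]
  cbar <- Ubar[, c, drop = FALSE]
  sigbar <- matrix(0, n, length(u))
  Sbar <- matrix(0, n, length(u))
  Tbar <- matrix(0, n, length(u))
  # execution went k = ls..1, so backprop ascends k
  for (k in seq_len(ls)) {
    st <- cache$steps[[k]]
    if (eps > 0) {
      # x_u = t + a G(M)_u with M = (t, c)
      Vg <- matrix(0, n, D); Vg[, u] <- a * ubar
      Xb <- tgt_hess_vp(target, st$M, Vg)
      Wh <- matrix(0, n, D); Wh[, u] <- a * lambda / (1 + a * st$H)
      Xb <- Xb + tgt_dhess_vp(target, st$M, Wh)
      tbar <- ubar + Xb[, u, drop = FALSE]
      cbar <- cbar + Xb[, c, drop = FALSE]
    } else {
      tbar <- ubar
    }
    sigbar <- sigbar - tbar * eps * cache$es
    if (k == ls) {
      # t = (x_in - T) e^{-S} - eps e^{sigma}; logdet term -sum(S)
      ubar <- tbar * cache$emS
      Tbar <- Tbar - tbar * cache$emS
      Sbar <- Sbar - tbar * (st$xu_in - cache$T$out) * cache$emS - lambda
    } else {
      ubar <- tbar
    }
  }
  bs <- mlp_backward(cond$sigma, cache$sig, sigbar * sbound_deriv(cache$sigb))
  bS <- mlp_backward(cond$S, cache$S, Sbar * sbound_deriv(cache$Sb))
  bT <- mlp_backward(cond$T, cache$T, Tbar)
  cbar <- cbar + bs$Xbar + bS$Xbar + bT$Xbar
  Xbar <- matrix(0, n, D)
  Xbar[, u] <- ubar
  Xbar[, c] <- cbar
  list(Xbar = Xbar,
       grads = list(sigma = list(W = bs$dW, b = bs$db),
                    S = list(W = bS$dW, b = bS$db),
                    T = list(W = bT$dW, b = bT$db)))
}

# parameter trees ------------------------------------------------------------

layer_params <- function(layer) list(cond_b = layer$cond_b, cond_a = layer$cond_a)

stack_params <- function(stack) lapply(stack$layers, layer_params)

stack_set_params <- function(stack, params) {
  for (t in seq_along(stack$layers)) {
    stack$layers[[t]]$cond_b <- params[[t]]$cond_b
    stack$layers[[t]]$cond_a <- params[[t]]$cond_a
  }
  stack
}

#' Number of trainable parameters in a flow stack
#' @param stack a [flow_stack()].
#' @return integer parameter count.
#' @export
n_params <- function(stack) length(tree_flatten(stack_params(stack)))
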