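# Target distributions as energy functions U(x) = -log p_unt(x), with analytic
# gradients and diagonal second derivatives. All batch callables operate on an
# n x D matrix of points and are vectorized over rows.

#' Construct a target distribution
#'
#' A target is an unnormalized density `p_unt(x) = exp(-U(x))` described by its
#' energy `U`, gradient and diagonal second derivatives. Every sampler and loss
#' in the package consumes this object. The batch callables receive an
#' `n x dim` matrix and return a length-`n` vector (energy) or an `n x dim`
#' matrix (gradient, diagonal Hessian).
#'
#' @param name short identifier.
#' @param dim dimension D (positive integer).
#' @param energy function(X) -> length-n vector of energies (nats).
#' @param grad_energy function(X) -> n x D matrix of gradients.
#' @param diag_hess_energy function(X) -> n x D matrix of second derivatives
#'   d^2 U / dx_i^2.
#' @param log_norm_const optional known log normalizer ln Z with
#'   `Z = int exp(-U)`; `NULL` when unknown.
#' @param hess_vp optional function(X, V) -> n x D matrix of Hessian-vector
#'   products `H(x_i) v_i` per row; a central-difference fallback on
#'   `grad_energy` is used when absent.
#' @param dhess_vp optional function(X, W) -> n x D matrix whose rows are the
#'   gradients (w.r.t. x) of `sum_i W[,i] * H_ii(x)`; finite-difference
#'   fallback on `diag_hess_energy` when absent.
#' @param sampler optional function(n) returning n exact draws (available for
#'   Gaussians and mixtures; used by diagnostics cross-checks).
#' @param grad_dhess optional function(X) -> list(G, H) returning gradient and
#'   diagonal Hessian together (lets targets share intermediates on the
#'   sampler's hot path).
#' @return an object of class `"target_distribution"`.
#' @export
target_distribution <- function(name, dim, energy, grad_energy, diag_hess_energy,
                                log_norm_const = NULL, hess_vp = NULL,
                                dhess_vp = NULL, sampler = NULL,
                                grad_dhess = NULL) {
  stopifnot(is.character(name), length(name) == 1L)
  dim <- as.integer(dim)
  if (dim < 1L) stop("target dimension must be a positive integer")
  structure(list(
    name = name, dim = dim,
    energy = energy, grad_energy = grad_energy,
    diag_hess_energy = diag_hess_energy,
    log_norm_const = log_norm_const,
    hess_vp = hess_vp, dhess_vp = dhess_vp,
    sampler = sampler, grad_dhess = grad_dhess
  ), class = "target_distribution")
}

#' @export
print.target_distribution <- function(x, ...) {
  cat("Target distribution: ", x$name, " (D = ", x$dim, ")\n", sep = "")
  if (!is.null(x$log_norm_const))
    cat("  known log normalizer ln Z =", format(x$log_norm_const), "\n")
  invisible(x)
}

# coerce a vector or matrix to an n x dim matrix of points
as_points <- function(x, dim) {
  if (is.null(base::dim(x))) {
    if (length(x) != dim)
      stop("point has length ", length(x), " but target dimension is ", dim)
    matrix(x, nrow = 1L)
  } else {
    x <- as.matrix(x)
    if (ncol(x) != dim)
      stop("points have ", ncol(x), " columns but target dimension is ", dim)
    x
  }
}

#' Evaluate a target's energy, gradient or diagonal Hessian
#'
#' Convenience accessors accepting a single point (vector) or a matrix of
#' points (one per row). `energy` returns a scalar/vector, the others a matrix
#' with one row per point (dropped to a vector for a single point).
#'
#' @param target a [target_distribution()].
#' @param x point (length-D vector) or n x D matrix.
#' @return energies, gradients or diagonal second derivatives.
#' @export
energy <- function(target, x) {
  X <- as_points(x, target$dim)
  u <- target$energy(X)
  if (is.null(base::dim(x))) u[[1L]] else u
}

#' @rdname energy
#' @export
grad_energy <- function(target, x) {
  X <- as_points(x, target$dim)
  G <- target$grad_energy(X)
  if (is.null(base::dim(x))) drop(G) else G
}

#' @rdname energy
#' @export
diag_hess_energy <- function(target, x) {
  X <- as_points(x, target$dim)
  H <- target$diag_hess_energy(X)
  if (is.null(base::dim(x))) drop(H) else H
}

# ---- internal batched calls with finite-difference fallbacks --------------

tgt_energy <- function(target, X) target$energy(X)
tgt_grad   <- function(target, X) target$grad_energy(X)
tgt_dhess  <- function(target, X) target$diag_hess_energy(X)

# gradient and diagonal Hessian in one pass (targets with shared
# intermediate computations override this through the grad_dhess field)
tgt_grad_dhess <- function(target, X) {
  if (!is.null(target$grad_dhess)) return(target$grad_dhess(X))
  list(G = target$grad_energy(X), H = target$diag_hess_energy(X))
}

# rows: H(x_i) v_i. Central difference of the gradient along v when no
# analytic product is available.
tgt_hess_vp <- function(target, X, V) {
  if (!is.null(target$hess_vp)) return(target$hess_vp(X, V))
  vn <- sqrt(rowSums(V^2))
  scale <- ifelse(vn > 0, vn, 1)
  Vu <- V / scale
  h <- 1e-5 * (1 + sqrt(rowSums(X^2)))
  Gp <- target$grad_energy(X + h * Vu)
  Gm <- target$grad_energy(X - h * Vu)
  (Gp - Gm) / (2 * h) * vn
}

# rows: gradient w.r.t. x of sum_i W[,i] * H_ii(x). Coordinate-wise central
# difference of diag_hess_energy when no analytic form is available.
tgt_dhess_vp <- function(target, X, W) {
  if (!is.null(target$dhess_vp)) return(target$dhess_vp(X, W))
  D <- ncol(X)
  out <- matrix(0, nrow(X), D)
  for (j in seq_len(D)) {
    h <- 1e-5 * (1 + abs(X[, j]))
    Xp <- X; Xp[, j] <- Xp[, j] + h
    Xm <- X; Xm[, j] <- Xm[, j] - h
    out[, j] <- rowSums(W * (target$diag_hess_energy(Xp) -
                             target$diag_hess_energy(Xm))) / (2 * h)
  }
  out
}

# ---- analytic catalog ------------------------------------------------------

#' Ring-shaped energy
#'
#' `U(x) = (x1^2 + x2^2 - offset)^2 / 0.32`; the density concentrates on the
#' circle of squared radius `offset`. `offset = 2` is the small ring,
#' `offset = 3` the enlarged one.
#'
#' @param x length-2 vector or n x 2 matrix.
#' @param offset positive squared radius of the ring.
#' @return energy value(s).
#' @export
ring_energy <- function(x, offset = 2) {
  if (offset <= 0) stop("ring offset must be positive")
  X <- as_points(x, 2L)
  u <- (rowSums(X^2) - offset)^2 / 0.32
  if (is.null(base::dim(x))) u[[1L]] else u
}

#' Ring target distribution
#' @param offset positive squared radius (2 = small ring, 3 = large ring).
#' @return a [target_distribution()].
#' @export
target_ring <- function(offset = 2) {
  if (offset <= 0) stop("ring offset must be positive")
  target_distribution(
    name = if (offset == 2) "ring" else sprintf("ring(%g)", offset), dim = 2L,
    energy = function(X) (rowSums(X^2) - offset)^2 / 0.32,
    grad_energy = function(X) {
      r <- rowSums(X^2) - offset
      4 * X * r / 0.32
    },
    diag_hess_energy = function(X) {
      r <- rowSums(X^2) - offset
      (4 * r + 8 * X^2) / 0.32
    }
  )
}

#' Rough-well energy
#'
#' `U(x) = 0.5 x'x + eta * sum_i cos(x_i / eta)`: a quadratic well with a
#' rapidly oscillating small-amplitude perturbation (default `eta = 0.01`).
#'
#' @param x vector or matrix of points (any dimension).
#' @param eta positive roughness scale.
#' @return energy value(s).
#' @export
rough_well_energy <- function(x, eta = 0.01) {
  if (eta <= 0) stop("eta must be positive")
  X <- if (is.null(base::dim(x))) matrix(x, nrow = 1L) else as.matrix(x)
  u <- 0.5 * rowSums(X^2) + eta * rowSums(cos(X / eta))
  if (is.null(base::dim(x))) u[[1L]] else u
}

#' Rough-well target distribution
#' @param dim dimension (default 2).
#' @param eta positive roughness scale (default 0.01).
#' @return a [target_distribution()].
#' @export
target_rough_well <- function(dim = 2L, eta = 0.01) {
  if (eta <= 0) stop("eta must be positive")
  target_distribution(
    name = "rough-well", dim = dim,
    energy = function(X) 0.5 * rowSums(X^2) + eta * rowSums(cos(X / eta)),
    grad_energy = function(X) X - sin(X / eta),
    diag_hess_energy = function(X) 1 - cos(X / eta) / eta,
    # Hessian is diagonal; third derivatives are diagonal too.
    hess_vp = function(X, V) V * (1 - cos(X / eta) / eta),
    dhess_vp = function(X, W) W * sin(X / eta) / eta^2
  )
}

#' Gaussian funnel energy
#'
#' Neal-style funnel: `U(x) = x1^2/(2 sigma^2) + x2^2/(2 exp(x1))
#' + 0.5 log(2 pi exp(x1))`. The first coordinate is marginally
#' `N(0, sigma^2)`; the second is conditionally Gaussian with variance
#' `exp(x1)`.
#'
#' @param x length-2 vector or n x 2 matrix.
#' @param sigma positive scale of the first coordinate (default 1).
#' @return energy value(s).
#' @export
funnel_energy <- function(x, sigma = 1) {
  if (sigma <= 0) stop("sigma must be positive")
  X <- as_points(x, 2L)
  u <- X[, 1]^2 / (2 * sigma^2) + X[, 2]^2 * exp(-X[, 1]) / 2 +
    0.5 * (log(2 * pi) + X[, 1])
  if (is.null(base::dim(x))) u[[1L]] else u
}

#' Gaussian funnel target distribution
#' @param sigma positive scale of the funnel's neck coordinate.
#' @return a [target_distribution()] with known normalizer
#'   `ln Z = 0.5 log(2 pi) + log(sigma)`.
#' @export
target_funnel <- function(sigma = 1) {
  if (sigma <= 0) stop("sigma must be positive")
  target_distribution(
    name = "funnel", dim = 2L,
    energy = function(X)
      X[, 1]^2 / (2 * sigma^2) + X[, 2]^2 * exp(-X[, 1]) / 2 +
        0.5 * (log(2 * pi) + X[, 1]),
    grad_energy = function(X) {
      e <- exp(-X[, 1])
      cbind(X[, 1] / sigma^2 - X[, 2]^2 * e / 2 + 0.5, X[, 2] * e)
    },
    diag_hess_energy = function(X) {
      e <- exp(-X[, 1])
      cbind(1 / sigma^2 + X[, 2]^2 * e / 2, e)
    },
    log_norm_const = 0.5 * log(2 * pi) + log(sigma),
    sampler = function(n) {
      x1 <- stats::rnorm(n, 0, sigma)
      cbind(x1, stats::rnorm(n, 0, exp(x1 / 2)))
    }
  )
}

#' Mixture-of-Gaussians energy
#'
#' `U(x) = -log sum_k w_k N(x | mu_k, I)` with unit-covariance components,
#' evaluated with log-sum-exp stabilization. The density is normalized, so the
#' corresponding target has `log_norm_const = 0`.
#'
#' @param x point or matrix of points.
#' @param weights nonnegative mixture weights summing to 1.
#' @param means list of component mean vectors, all of the same length as `x`.
#' @return energy value(s).
#' @export
mog_energy <- function(x, weights, means) {
  tg <- target_mog(weights, means)
  energy(tg, x)
}

#' Mixture-of-Gaussians target distribution
#' @inheritParams mog_energy
#' @return a [target_distribution()] with exact sampler.
#' @export
target_mog <- function(weights, means) {
  if (any(weights < 0)) stop("mixture weights must be nonnegative")
  if (abs(sum(weights) - 1) > 1e-12) stop("mixture weights must sum to 1")
  means <- lapply(means, as.numeric)
  D <- length(means[[1L]])
  if (any(vapply(means, length, 1L) != D)) stop("component means must share a dimension")
  K <- length(weights)
  lw <- log(weights)
  const <- -0.5 * D * log(2 * pi)

  # centered points, per-point log component densities, responsibilities
  center <- function(X, k) X - rep(means[[k]], each = nrow(X))
  comp_logs <- function(X) {
    L <- matrix(0, nrow(X), K)
    for (k in seq_len(K))
      L[, k] <- lw[k] + const - 0.5 * rowSums(center(X, k)^2)
    L
  }
  resp <- function(X) {
    L <- comp_logs(X)
    m <- L[, 1L]
    for (k in seq_len(K)[-1L]) m <- pmax(m, L[, k])
    E <- exp(L - m)
    rs <- rowSums(E)
    list(logp = m + log(rs), R = E / rs)
  }

  target_distribution(
    name = "mog", dim = D,
    energy = function(X) -resp(X)$logp,
    grad_energy = function(X) {
      R <- resp(X)$R
      G <- matrix(0, nrow(X), D)
      for (k in seq_len(K)) G <- G + R[, k] * sweep(X, 2L, means[[k]])
      G
    },
    diag_hess_energy = function(X) {
      R <- resp(X)$R
      G <- matrix(0, nrow(X), D)   # grad
      S2 <- matrix(0, nrow(X), D)  # sum_k r_k m_k^2
      for (k in seq_len(K)) {
        Mk <- center(X, k)
        G <- G + R[, k] * Mk
        S2 <- S2 + R[, k] * Mk^2
      }
      1 - S2 + G^2
    },
    grad_dhess = function(X) {
      R <- resp(X)$R
      G <- matrix(0, nrow(X), D)
      S2 <- matrix(0, nrow(X), D)
      for (k in seq_len(K)) {
        Mk <- center(X, k)
        G <- G + R[, k] * Mk
        S2 <- S2 + R[, k] * Mk^2
      }
      list(G = G, H = 1 - S2 + G^2)
    },
    hess_vp = function(X, V) {
      R <- resp(X)$R
      G <- matrix(0, nrow(X), D)
      HV <- V
      for (k in seq_len(K)) {
        Mk <- center(X, k)
        G <- G + R[, k] * Mk
        HV <- HV - R[, k] * rowSums(Mk * V) * Mk
      }
      HV + rowSums(G * V) * G
    },
    # gradient w.r.t. x of sum_i W[,i] H_ii(x): the third-derivative
    # contraction d H_ii / d x_j = -sum_k r_k (g_j - m_kj) m_ki^2
    #   + 2 g_i^2 g_j - 2 g_i C_ij, with C_ij = sum_k r_k m_ki m_kj
    dhess_vp = function(X, W) {
      R <- resp(X)$R
      n <- nrow(X)
      G <- matrix(0, n, D)
      Ms <- vector("list", K)
      for (k in seq_len(K)) {
        Ms[[k]] <- center(X, k)
        G <- G + R[, k] * Ms[[k]]
      }
      A <- W * G                       # a_i = W_i g_i per row
      q_sum <- numeric(n)              # sum_k r_k q_k, q_k = sum_i W_i m_ki^2
      out <- matrix(0, n, D)
      for (k in seq_len(K)) {
        qk <- rowSums(W * Ms[[k]]^2)
        q_sum <- q_sum + R[, k] * qk
        out <- out + (R[, k] * qk) * Ms[[k]] -
          2 * (R[, k] * rowSums(A * Ms[[k]])) * Ms[[k]]
      }
      out - q_sum * G + 2 * rowSums(W * G^2) * G
    },
    log_norm_const = 0,
    sampler = function(n) {
      comp <- sample.int(K, n, replace = TRUE, prob = weights)
      M <- do.call(rbind, means)[comp, , drop = FALSE]
      M + matrix(stats::rnorm(n * D), n, D)
    }
  )
}

#' General Gaussian target
#'
#' Multivariate normal `N(mean, cov)` as a target with constant Hessian and
#' exact normalizer.
#'
#' @param mean mean vector.
#' @param cov covariance matrix (positive definite).
#' @param name identifier.
#' @return a [target_distribution()] with exact sampler.
#' @export
target_gaussian <- function(mean, cov, name = "gaussian") {
  mean <- as.numeric(mean)
  D <- length(mean)
  cov <- as.matrix(cov)
  stopifnot(nrow(cov) == D, ncol(cov) == D)
  ev <- eigen(cov, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev <= 0)) stop("covariance must be positive definite")
  P <- solve(cov)
  L <- chol(cov)  # upper triangular, cov = t(L) %*% L
  ldet <- sum(log(ev))
  dP <- diag(P)
  target_distribution(
    name = name, dim = D,
    energy = function(X) {
      M <- sweep(X, 2L, mean)
      0.5 * rowSums((M %*% P) * M)
    },
    grad_energy = function(X) sweep(X, 2L, mean) %*% P,
    diag_hess_energy = function(X) matrix(dP, nrow(X), D, byrow = TRUE),
    hess_vp = function(X, V) V %*% P,
    dhess_vp = function(X, W) matrix(0, nrow(X), D),
    log_norm_const = 0.5 * D * log(2 * pi) + 0.5 * ldet,
    sampler = function(n)
      sweep(matrix(stats::rnorm(n * D), n, D) %*% L, 2L, mean, "+")
  )
}

#' Ill-conditioned diagonal Gaussian
#'
#' Zero-mean Gaussian whose diagonal variances are log-linearly spaced between
#' `10^-2` and `10^2` across the D coordinates.
#'
#' @param dim dimension D >= 2.
#' @return a [target_distribution()].
#' @export
target_gaussian_ill <- function(dim = 2L) {
  if (dim < 2L) stop("ill-conditioned Gaussian needs D >= 2")
  v <- 10^seq(-2, 2, length.out = dim)
  target_gaussian(rep(0, dim), diag(v, dim), name = "icg")
}

#' Strongly correlated Gaussian
#'
#' A diagonal Gaussian with variances (100, 0.01) rotated by pi/4, giving
#' covariance `[[50.005, 49.995], [49.995, 50.005]]`; optionally with the
#' mean shifted to (10, 10).
#'
#' @param shifted logical; move the mean from (0,0) to (10,10).
#' @return a [target_distribution()].
#' @export
target_gaussian_correlated <- function(shifted = FALSE) {
  th <- pi / 4
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2L, 2L)
  S <- R %*% diag(c(100, 0.01)) %*% t(R)
  mu <- if (shifted) c(10, 10) else c(0, 0)
  target_gaussian(mu, S, name = if (shifted) "scg-shifted" else "scg")
}

#' Wrap a user-supplied unnormalized log-density as a target
#'
#' The energy is the negated log-density; gradient and diagonal second
#' derivatives are obtained by numerical differentiation (central differences
#' via pracma). Intended both as the entry point for custom posteriors and as
#' an independent oracle against the closed-form catalog.
#'
#' @param log_density_unnorm function(x) -> scalar unnormalized log-density for
#'   a single length-`dim` vector.
#' @param dim dimension.
#' @param name identifier.
#' @return a [target_distribution()] without known normalizer.
#' @export
wrap_log_density <- function(log_density_unnorm, dim, name = "custom") {
  dim <- as.integer(dim)
  probe <- log_density_unnorm(rep(0, dim))
  if (!is.finite(probe))
    stop("log-density is not finite at the origin; supply a valid unnormalized log-density")
  u1 <- function(x) -log_density_unnorm(x)
  target_distribution(
    name = name, dim = dim,
    energy = function(X) apply(X, 1L, u1),
    grad_energy = function(X)
      t(apply(X, 1L, function(x) pracma::grad(u1, x))),
    diag_hess_energy = function(X)
      t(apply(X, 1L, function(x) diag(pracma::hessian(u1, x))))
  )
}

#' Look up a catalog target by name
#'
#' Registry used by the command-line interface and configs. Names:
#' `ring`, `ring-large`, `icg`, `scg`, `scg-shifted`, `rough-well`, `funnel`,
#' `mog1` (equal-weight modes at +/-(2.5, -2.5)), `mog2` (0.88/0.12 modes at
#' +/-(4, -4)), `blr` (requires `data`, a [labeled_table()]).
#'
#' @param name target name.
#' @param dim dimension for families where it is free (`icg`, `rough-well`).
#' @param data a [labeled_table()] for `blr`.
#' @return a [target_distribution()].
#' @export
get_target <- function(name, dim = 2L, data = NULL) {
  switch(name,
    "ring"        = target_ring(2),
    "ring-large"  = target_ring(3),
    "icg"         = target_gaussian_ill(dim),
    "scg"         = target_gaussian_correlated(FALSE),
    "scg-shifted" = target_gaussian_correlated(TRUE),
    "rough-well"  = target_rough_well(dim),
    "funnel"      = target_funnel(1),
    "mog1"        = target_mog(c(0.5, 0.5), list(c(2.5, -2.5), c(-2.5, 2.5))),
    "mog2"        = target_mog(c(0.88, 0.12), list(c(4, -4), c(-4, 4))),
    "blr"         = {
      if (is.null(data)) stop("target 'blr' requires a labeled_table via `data`")
      target_blr(data)
    },
    stop("unknown target name: ", name)
  )
}
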