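# Coupling-layer mechanics: identity reduction, triangular structure,
# round-trip inversion order, log-determinants, flow density.

test_that("eps = 0 with zero conditioners is the exact identity", {
  tg <- target_gaussian_ill(2)
  st <- flow_stack(tg, n_layers = 3, epsilon = 0, hidden = c(8, 8), seed = 1)
  set.seed(2)
  X <- matrix(rnorm(20), 10, 2)
  fw <- flow_forward(st, X)
  expect_identical(fw$z, X)
  expect_identical(fw$fwd_logdet, numeric(10))
  iv <- flow_inverse(st, X)
  expect_identical(iv$x, X)
  expect_identical(iv$inv_logdet, numeric(10))
  expect_equal(flow_log_prob(st, X), nflmc:::base_log_density(st$base, X))
})

test_that("pure Langevin half-step updates one block by the printed rule", {
  # U = 0.5||x||^2, D = 2, x = (1, 2), eps = 0.1, sigma == 0:
  # updated coordinate -> 2 - (0.1^2/2)*2 + 0.1*exp(0) = 2.09
  tg <- target_gaussian(c(0, 0), diag(2))
  st <- flow_stack(tg, n_layers = 1, epsilon = 0.1, langevin_steps = 1,
                   hidden = c(4), seed = 3)
  ly <- st$layers[[1]]
  out <- langevin_half_step(c(1, 2), "first", ly, tg)
  expect_equal(out[2], 2.09)
  expect_identical(out[1], 1)     # complementary block untouched
  out2 <- langevin_half_step(c(1, 2), "second", ly, tg)
  expect_identical(out2[2], 2)
  expect_equal(out2[1], 1 - 0.005 * 1 + 0.1)
  # eps = 0 -> identity
  st0 <- flow_stack(tg, n_layers = 1, epsilon = 0, hidden = c(4), seed = 3)
  expect_identical(langevin_half_step(c(1, 2), "first", st0$layers[[1]], tg),
                   c(1, 2))
})

test_that("blocks update triangularly within a layer", {
  tg <- target_ring(2)
  st <- tiny_stack(tg, epsilon = 0.05, n_layers = 1L, sd = 0.3)
  ly <- st$layers[[1]]
  set.seed(4)
  X <- matrix(rnorm(12, sd = 1.5), 6, 2)
  # phase 1 leaves the conditioning block bitwise unchanged
  p1 <- nflmc:::phase_forward(X, ly$epsilon, ly$langevin_steps, ly$ib, ly$ia,
                              ly$cond_b, tg)
  expect_identical(p1$X[, ly$ia], X[, ly$ia])
  expect_false(any(p1$X[, ly$ib] == X[, ly$ib]))
  # phase 2 leaves the first-updated block unchanged
  p2 <- nflmc:::phase_forward(p1$X, ly$epsilon, ly$langevin_steps, ly$ia,
                              ly$ib, ly$cond_a, tg)
  expect_identical(p2$X[, ly$ib], p1$X[, ly$ib])
})

test_that("eps = 0 constant-S layer has the analytic affine log-det", {
  tg <- target_gaussian(c(0, 0), diag(2))
  st <- flow_stack(tg, n_layers = 1, epsilon = 0, hidden = c(4), seed = 5)
  # set the S-net output biases so the (tanh-clamped) scale is exactly s
  s <- 0.3
  raw <- nflmc:::COND_BOUND * atanh(s / nflmc:::COND_BOUND)
  ly <- st$layers[[1]]
  ly$cond_b$S$b[[length(ly$cond_b$S$b)]] <- raw
  ly$cond_a$S$b[[length(ly$cond_a$S$b)]] <- raw
  st$layers[[1]] <- ly
  set.seed(6)
  X <- matrix(rnorm(10), 5, 2)
  fw <- forward_layer(X, ly, tg)
  expect_equal(fw$fwd_logdet, rep(s * 2, 5))   # s * D with D = 2
  # exact inversion and opposite log-det at eps = 0
  iv <- inverse_layer(fw$z, ly, tg)
  expect_equal(iv$x, X, tolerance = 1e-12)
  expect_equal(iv$inv_logdet, -fw$fwd_logdet, tolerance = 1e-12)
  # flow log-density equals the closed-form affine pushforward density:
  # z = x * e^s (+ shift-free here), so log p(z) = log N(z e^{-s}) - s D
  lp <- flow_log_prob(st, fw$z)
  expect_equal(lp, nflmc:::base_log_density(st$base, X) - 2 * s,
               tolerance = 1e-12)
})

test_that("round-trip inversion error shrinks at least 3x per eps halving", {
  tg <- target_gaussian(c(0, 0), diag(2))
  set.seed(7)
  X <- matrix(rnorm(200), 100, 2)
  err <- sapply(c(0.2, 0.1, 0.05), function(eps) {
    st <- tiny_stack(tg, epsilon = eps, n_layers = 2L, sd = 0.1, seed = 8)
    fw <- flow_forward(st, X)
    iv <- flow_inverse(st, fw$z)
    max(sqrt(rowSums((iv$x - X)^2)))
  })
  expect_gte(err[1] / err[2], 3)
  expect_gte(err[2] / err[3], 3)
})

test_that("fused-step inverse log-det matches the printed per-coordinate form", {
  # S = 0, quadratic U with identity Hessian: each fused inverse-step term is
  # log(1 + eps^2/2) per coordinate; Ls = 1 so one fused step per block
  tg <- target_gaussian(c(0, 0), diag(2))
  eps <- 0.2
  st <- flow_stack(tg, n_layers = 1, epsilon = eps, langevin_steps = 1,
                   hidden = c(4), seed = 9)
  set.seed(10)
  z <- rnorm(2)
  iv <- inverse_layer(z, st$layers[[1]], tg)
  expect_equal(iv$inv_logdet, 2 * log(1 + eps^2 / 2), tolerance = 1e-12)
})

test_that("diagonal forward log-det matches the numerical full Jacobian", {
  # exact on targets with diagonal Hessian
  for (nm in c("icg", "rough-well")) {
    tg <- get_target(nm)
    st <- tiny_stack(tg, epsilon = 0.05, langevin_steps = 2L, n_layers = 2L,
                     sd = 0.2, seed = 11)
    set.seed(12)
    for (r in 1:5) {
      x <- rnorm(2, sd = 0.8)
      fw <- flow_forward(st, x)
      J <- pracma::jacobian(function(v) flow_forward(st, v)$z, x)
      expect_lt(abs(fw$fwd_logdet - log(abs(det(J)))), 1e-6,
                label = paste("logdet vs numerical full Jacobian,", nm))
    }
  }
})

test_that("forward and negated inverse log-dets agree to O(eps^2)", {
  tg <- target_gaussian_ill(2)
  set.seed(13)
  X <- matrix(rnorm(60, sd = 0.8), 30, 2)
  gap <- sapply(c(0.2, 0.1), function(eps) {
    st <- tiny_stack(tg, epsilon = eps, n_layers = 2L, sd = 0.1, seed = 14)
    fw <- flow_forward(st, X)
    iv <- flow_inverse(st, fw$z)
    max(abs(fw$fwd_logdet + iv$inv_logdet))
  })
  expect_gte(gap[1] / gap[2], 3)
})

test_that("a trained stack's density integrates to 1 on a 2-D grid", {
  tg <- target_gaussian(c(1.5, -1), diag(c(1.2, 0.8)))
  fit <- nflmc(tg, n_layers = 2, hidden = c(8, 8), epsilon = 0.05,
               iterations = 300, batch_size = 256, learning_rate = 0.01,
               seed = 15)
  mass <- quad2d_mass(function(G) flow_log_prob(fit$stack, G),
                      c(-8, 10, -9, 7), n_grid = 140L)
  expect_equal(mass, 1, tolerance = 2e-2)
})

test_that("sample_flow is seed-deterministic and fills the batch fields", {
  tg <- target_mog(c(0.5, 0.5), list(c(2.5, -2.5), c(-2.5, 2.5)))
  st <- tiny_stack(tg, epsilon = 0.05, sd = 0.1, seed = 16)
  b1 <- sample_flow(st, 500, seed = 17)
  b2 <- sample_flow(st, 500, seed = 17)
  expect_identical(b1$points, b2$points)
  expect_identical(b1$log_q_flow, b2$log_q_flow)
  expect_equal(b1$log_target_unnorm, -energy(tg, b1$points))
  # identity stack: draws are exactly base draws with the base density
  st0 <- flow_stack(tg, n_layers = 2, epsilon = 0, hidden = c(4), seed = 18)
  b <- sample_flow(st0, 3000, seed = 19)
  set.seed(19)
  X0 <- nflmc:::base_sample(st0$base, 3000)
  expect_identical(b$points, X0)
  # CLT check on the mean of an identity stack
  expect_lt(max(abs(colMeans(b$points))), 3 / sqrt(3000) * 1.5)
})

test_that("one-dimensional targets are rejected", {
  tg1 <- target_gaussian(0, matrix(1, 1, 1))
  expect_error(flow_stack(tg1), "D >= 2")
})
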