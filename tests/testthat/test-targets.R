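# Analytic target catalog: energies, derivatives, normalizers.

test_that("ring energy matches direct substitution and vanishes on the ring", {
  expect_equal(ring_energy(c(sqrt(2), 0), offset = 2), 0)
  expect_equal(ring_energy(c(1, 1), offset = 2), 0)
  expect_equal(ring_energy(c(0, 0), offset = 2), 4 / 0.32) # = 12.5
  expect_equal(ring_energy(c(0, 0), offset = 2), 12.5)
  expect_error(ring_energy(c(1, 2, 3)), "length")
  expect_error(target_ring(-1), "positive")
})

test_that("rough-well energy is the quadratic well plus bounded ripple", {
  expect_equal(rough_well_energy(c(0, 0), eta = 0.01), 0.02)
  x <- c(0.01 * pi, 0.01 * pi)
  expect_equal(rough_well_energy(x, eta = 0.01), sum(x^2) / 2 - 0.02)
  set.seed(1)
  for (r in 1:20) {
    x <- rnorm(3, sd = 2)
    expect_lte(abs(rough_well_energy(x, 0.01) - sum(x^2) / 2), 0.01 * 3)
  }
  expect_error(rough_well_energy(c(0, 0), eta = 0), "positive")
})

test_that("funnel energy has the Gaussian-neck form and Gaussian x1 marginal", {
  expect_equal(funnel_energy(c(0, 0), sigma = 1), 0.5 * log(2 * pi),
               tolerance = 1e-12)
  # the x2 conditional is exactly Gaussian, so integrating it out of exp(-U)
  # leaves the unnormalized N(0, sigma^2) marginal exp(-x1^2 / (2 sigma^2))
  tg <- target_funnel(1)
  for (x1 in c(-1, 0, 0.7)) {
    m <- integrate(function(x2)
      exp(-energy(tg, cbind(x1, x2))), -Inf, Inf)$value
    expect_equal(m, exp(-x1^2 / 2), tolerance = 1e-6)
  }
})

test_that("mixture energy: symmetry, mode value, and weight ratio", {
  mu <- c(2.5, -2.5)
  w <- c(0.5, 0.5)
  means <- list(mu, -mu)
  set.seed(2)
  for (r in 1:10) {
    x <- rnorm(2, sd = 3)
    expect_equal(mog_energy(x, w, means), mog_energy(-x, w, means))
  }
  # at the mode the far component is negligible (distance^2 = 50):
  # U ~ -log(0.5 / (2 pi)) = log(4 pi)
  expect_equal(mog_energy(mu, w, means), log(4 * pi), tolerance = 1e-6)
  # asymmetric weights: density ratio at the two means ~ 0.88 / 0.12
  tg2 <- target_mog(c(0.88, 0.12), list(c(4, -4), c(-4, 4)))
  lr <- energy(tg2, c(-4, 4)) - energy(tg2, c(4, -4))
  expect_equal(exp(-lr), 0.12 / 0.88, tolerance = 1e-10)
  expect_error(target_mog(c(0.7, 0.2), list(c(0, 0), c(1, 1))), "sum to 1")
})

test_that("single-component mixture reduces to the Gaussian energy", {
  tg1 <- target_mog(1, list(c(1, -2)))
  tgg <- target_gaussian(c(1, -2), diag(2))
  set.seed(3)
  X <- matrix(rnorm(40), 20, 2)
  # equal up to the Gaussian's normalizing constant
  diff <- energy(tg1, X) - energy(tgg, X)
  expect_equal(max(diff) - min(diff), 0, tolerance = 1e-12)
  expect_equal(diff[1], log(2 * pi), tolerance = 1e-12)
})

test_that("correlated Gaussian has the printed covariance and eigenvalues", {
  tg <- target_gaussian_correlated()
  # recover covariance from the constant Hessian: cov = solve(H)
  H <- matrix(0, 2, 2)
  for (j in 1:2) {
    v <- matrix(0, 1, 2); v[1, j] <- 1
    H[, j] <- drop(tg$hess_vp(matrix(0, 1, 2), v))
  }
  S <- solve(H)
  expect_equal(S, matrix(c(50.005, 49.995, 49.995, 50.005), 2, 2),
               tolerance = 1e-10)
  expect_equal(sort(eigen(S)$values), c(0.01, 100), tolerance = 1e-8)
  # shifted variant: same shape, mean at (10,10)
  tgs <- target_gaussian_correlated(shifted = TRUE)
  expect_equal(drop(grad_energy(tgs, c(10, 10))), c(0, 0), tolerance = 1e-10)
})

test_that("ill-conditioned Gaussian spans variances 1e-2..1e2 log-linearly", {
  tg <- target_gaussian_ill(2)
  H <- diag_hess_energy(tg, c(0, 0))
  expect_equal(sort(1 / H), c(0.01, 100), tolerance = 1e-10)
  tg5 <- target_gaussian_ill(5)
  expect_equal(1 / diag_hess_energy(tg5, rep(0, 5)),
               10^seq(-2, 2, length.out = 5), tolerance = 1e-10)
  expect_error(target_gaussian_ill(1), "D >= 2")
})

test_that("gradients agree with central differences at random points", {
  set.seed(4)
  for (nm in c("ring", "ring-large", "icg", "scg", "scg-shifted",
               "rough-well", "funnel", "mog1", "mog2")) {
    tg <- get_target(nm)
    for (r in 1:5) {
      x <- rnorm(tg$dim, sd = 1.5)
      g <- grad_energy(tg, x)
      gf <- fd_grad(tg, x)
      expect_equal(g, gf, tolerance = 1e-4,
                   label = paste("grad of", nm))
    }
  }
})

test_that("diagonal Hessians agree with differenced gradients", {
  set.seed(5)
  for (nm in c("ring", "icg", "scg", "rough-well", "funnel", "mog1", "mog2")) {
    tg <- get_target(nm)
    for (r in 1:5) {
      x <- rnorm(tg$dim, sd = 1.5)
      h <- diag_hess_energy(tg, x)
      hf <- fd_diag_hess(tg, x)
      expect_lt(max(abs(h - hf) / pmax(abs(hf), 1)), 1e-3,
                label = paste("diag hess of", nm))
    }
  }
})

test_that("known normalizers integrate exp(-U)/Z to 1 on a 2-D grid", {
  for (nm in c("funnel", "mog1")) {
    tg <- get_target(nm)
    sd_box <- if (nm == "funnel") c(-8, 8, -12, 12) else c(-8.5, 8.5, -8.5, 8.5)
    mass <- quad2d_mass(function(X) -tg$energy(X) - tg$log_norm_const,
                        sd_box, n_grid = 240L)
    expect_equal(mass, 1, tolerance = 1e-3, label = paste("mass of", nm))
  }
  # correlated Gaussian: integrate in the rotated eigenbasis (the +-8 sd box
  # in original coordinates is badly aligned with the 0.1-sd direction)
  tg <- target_gaussian(c(0, 0), diag(c(100, 0.01)), name = "diag")
  mass <- quad2d_mass(function(X) -tg$energy(X) - tg$log_norm_const,
                      c(-80, 80, -0.8, 0.8), n_grid = 400L)
  expect_equal(mass, 1, tolerance = 1e-3)
})

test_that("numerical-differentiation wrapper matches closed forms", {
  tg <- wrap_log_density(function(x) -0.5 * sum(x^2), dim = 3)
  set.seed(6)
  x <- rnorm(3)
  expect_equal(grad_energy(tg, x), x, tolerance = 1e-6)
  expect_equal(diag_hess_energy(tg, x), rep(1, 3), tolerance = 1e-4)
  # cross-implementation agreement with the ring catalog member
  tgr <- wrap_log_density(function(x) -ring_energy(x, 2), dim = 2)
  cat_ring <- target_ring(2)
  for (r in 1:20) {
    x <- rnorm(2, sd = 2)
    expect_equal(energy(tgr, x), energy(cat_ring, x), tolerance = 1e-10)
    expect_equal(grad_energy(tgr, x), grad_energy(cat_ring, x),
                 tolerance = 1e-5)
  }
  expect_error(wrap_log_density(function(x) log(-1), dim = 2), "finite")
})

test_that("registry rejects unknown names and blr without data", {
  expect_error(get_target("nope"), "unknown target")
  expect_error(get_target("blr"), "labeled_table")
})
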