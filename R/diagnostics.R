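# Sampler-quality diagnostics: lagged autocorrelation, effective sample size,
# maximum mean discrepancy, and a nearest-mode mass estimator.

#' Per-dimension autocorrelation of a chain
#'
#' Stationary single-mean estimator
#' `rho(s) = sum_t (x_t - xbar)(x_{t+s} - xbar) / sum_t (x_t - xbar)^2`
#' for lags `0..max_lag` (this is what [stats::acf()] computes), per dimension.
#'
#' @param chain N x D matrix (or length-N vector) of ordered draws.
#' @param max_lag largest lag M (1 <= M < N).
#' @return (max_lag + 1) x D matrix of autocorrelations, rows named by lag;
#'   row "0" is identically 1.
#' @export
chain_acf <- function(chain, max_lag = 30L) {
  X <- if (is.null(dim(chain))) matrix(chain, ncol = 1L) else as.matrix(chain)
  N <- nrow(X)
  if (max_lag < 1L || N <= max_lag)
    stop("need N > max_lag >= 1")
  sds <- apply(X, 2L, stats::sd)
  if (any(sds == 0)) stop("autocorrelation undefined for a zero-variance chain")
  out <- sapply(seq_len(ncol(X)), function(j)
    drop(stats::acf(X[, j], lag.max = max_lag, plot = FALSE,
                    demean = TRUE)$acf))
  out <- matrix(out, nrow = max_lag + 1L)
  rownames(out) <- 0:max_lag
  colnames(out) <- colnames(X, do.NULL = FALSE, prefix = "x")
  out
}

#' Effective sample size
#'
#' `ESS = N / (1 + 2 * sum_{s=1}^{M} rho(s))` per dimension, with the
#' denominator clipped below at 1e-3 (negative autocorrelation sums can push
#' it to zero or below; clipped dimensions are flagged with a warning).
#'
#' @inheritParams chain_acf
#' @return list with `per_dim` (named vector), `mean` (average across
#'   dimensions) and `n` (chain length).
#' @export
ess <- function(chain, max_lag = 30L) {
  X <- if (is.null(dim(chain))) matrix(chain, ncol = 1L) else as.matrix(chain)
  rho <- chain_acf(X, max_lag)
  N <- nrow(X)
  denom <- 1 + 2 * colSums(rho[-1L, , drop = FALSE])
  clipped <- denom < 1e-3
  if (any(clipped))
    warning("ESS denominator clipped at 1e-3 for dimension(s) ",
            paste(which(clipped), collapse = ", "))
  denom <- pmax(denom, 1e-3)
  per_dim <- N / denom
  names(per_dim) <- colnames(rho)
  list(per_dim = per_dim, mean = mean(per_dim), n = N)
}

#' Squared maximum mean discrepancy
#'
#' Biased V-statistic (diagonal terms included)
#' `MMD^2 = mean k(x,x') - 2 mean k(x,y) + mean k(y,y')` with a Gaussian
#' kernel `k(a,b) = exp(-||a-b||^2 / (2 h^2))`. The default bandwidth `h` is
#' the median of the pooled pairwise distances of the two sets.
#'
#' @param X M x D matrix of draws.
#' @param Y N x D matrix of draws (same D).
#' @param bandwidth positive kernel bandwidth, or `"median"` for the median
#'   heuristic.
#' @return nonnegative scalar with attribute `"bandwidth"`.
#' @export
mmd2 <- function(X, Y, bandwidth = "median") {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (nrow(X) < 1L || nrow(Y) < 1L) stop("both sample sets must be nonempty")
  if (ncol(X) != ncol(Y)) stop("sample sets must share a dimension")
  Z <- rbind(X, Y)
  nz <- rowSums(Z^2)
  D2 <- outer(nz, nz, "+") - 2 * tcrossprod(Z)
  D2[D2 < 0] <- 0
  if (identical(bandwidth, "median")) {
    h <- stats::median(sqrt(D2[upper.tri(D2)]))
    if (!is.finite(h) || h <= 0) h <- 1
  } else {
    h <- as.numeric(bandwidth)
    if (h <= 0) stop("bandwidth must be positive")
  }
  K <- exp(-D2 / (2 * h^2))
  m <- nrow(X); n <- nrow(Y)
  ix <- seq_len(m); iy <- m + seq_len(n)
  val <- mean(K[ix, ix]) - 2 * mean(K[ix, iy, drop = FALSE]) + mean(K[iy, iy])
  structure(val, bandwidth = h)
}

#' Fraction of samples in the basin of the first mode
#'
#' Fraction of rows strictly nearer (Euclidean) `center1` than `center2`;
#' exact ties count toward `center1`.
#'
#' @param samples N x D matrix of draws.
#' @param center1,center2 distinct mode centers.
#' @return proportion in `[0, 1]`.
#' @export
mode_weight <- function(samples, center1, center2) {
  S <- as.matrix(samples)
  center1 <- as.numeric(center1); center2 <- as.numeric(center2)
  if (isTRUE(all.equal(center1, center2, tolerance = 0)))
    stop("mode centers must be distinct")
  d1 <- rowSums(sweep(S, 2L, center1)^2)
  d2 <- rowSums(sweep(S, 2L, center2)^2)
  mean(d1 <= d2)
}

#' Full diagnostics report for a chain of draws
#'
#' @param chain N x D matrix of ordered draws.
#' @param max_lag largest autocorrelation lag M.
#' @param reference optional matrix of reference draws for an MMD^2 entry.
#' @param bandwidth MMD kernel bandwidth (see [mmd2()]).
#' @return object of class `"nflmc_diagnostics"` with fields `acf`,
#'   `ess_per_dim`, `ess_mean`, `mmd2` (or `NULL`), `max_lag`, `n`.
#' @export
diagnose <- function(chain, max_lag = 30L, reference = NULL,
                     bandwidth = "median") {
  X <- if (is.null(dim(chain))) matrix(chain, ncol = 1L) else as.matrix(chain)
  rho <- chain_acf(X, max_lag)
  es <- ess(X, max_lag)
  mm <- if (!is.null(reference)) as.numeric(mmd2(X, as.matrix(reference),
                                                 bandwidth)) else NULL
  structure(list(acf = rho, ess_per_dim = es$per_dim, ess_mean = es$mean,
                 mmd2 = mm, max_lag = as.integer(max_lag), n = nrow(X)),
            class = "nflmc_diagnostics")
}

#' @export
print.nflmc_diagnostics <- function(x, ...) {
  cat("Chain diagnostics: N =", x$n, ", max lag M =", x$max_lag, "\n")
  cat("  ESS per dimension:", paste(format(round(x$ess_per_dim, 1)),
                                    collapse = ", "), "\n")
  cat("  mean ESS:", format(round(x$ess_mean, 1)), "\n")
  if (!is.null(x$mmd2)) cat("  MMD^2 vs reference:", format(x$mmd2), "\n")
  invisible(x)
}
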