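# Small feed-forward conditioner networks (ReLU hidden layers) with manual
# reverse-mode backpropagation, plus helpers to treat nested parameter lists
# as flat vectors (used by the optimizers and by finite-difference tests).

# He-initialized hidden layers; the final layer starts at zero so that a fresh
# coupling layer is the pure Langevin map.
mlp_init <- function(din, dout, hidden) {
  sizes <- c(din, hidden, dout)
  L <- length(sizes) - 1L
  W <- vector("list", L)
  b <- vector("list", L)
  for (l in seq_len(L)) {
    if (l < L) {
      W[[l]] <- matrix(stats::rnorm(sizes[l] * sizes[l + 1L], 0,
                                    sqrt(2 / sizes[l])), sizes[l], sizes[l + 1L])
    } else {
      W[[l]] <- matrix(0, sizes[l], sizes[l + 1L])
    }
    b[[l]] <- numeric(sizes[l + 1L])
  }
  list(W = W, b = b)
}

# X: n x din. Returns n x dout output; with keep = TRUE also the layer inputs
# needed for backprop.
mlp_forward <- function(mlp, X, keep = FALSE) {
  L <- length(mlp$W)
  ins <- if (keep) vector("list", L) else NULL
  Z <- X
  for (l in seq_len(L)) {
    if (keep) ins[[l]] <- Z
    A <- Z %*% mlp$W[[l]]
    A <- A + rep(mlp$b[[l]], each = nrow(A))
    Z <- if (l < L) pmax(A, 0) else A
  }
  if (keep) list(out = Z, ins = ins) else Z
}

# Ybar: n x dout cotangent on the output. Returns parameter gradients (same
# shape as mlp) and the cotangent on the input X.
mlp_backward <- function(mlp, cache, Ybar) {
  L <- length(mlp$W)
  dW <- vector("list", L)
  db <- vector("list", L)
  G <- Ybar
  for (l in rev(seq_len(L))) {
    Z <- cache$ins[[l]]
    dW[[l]] <- crossprod(Z, G)
    db[[l]] <- colSums(G)
    G <- G %*% t(mlp$W[[l]])
    if (l > 1L) G <- G * (cache$ins[[l]] > 0)
  }
  list(dW = dW, db = db, Xbar = G)
}

mlp_zero_grad <- function(mlp) {
  list(dW = lapply(mlp$W, function(w) array(0, dim(w))),
       db = lapply(mlp$b, function(v) numeric(length(v))))
}

# ---- parameter-tree utilities ---------------------------------------------

# apply f elementwise over two parallel nested lists of numerics
tree_map2 <- function(f, a, b) {
  if (is.list(a)) {
    out <- vector("list", length(a))
    names(out) <- names(a)
    for (i in seq_along(a)) out[[i]] <- tree_map2(f, a[[i]], b[[i]])
    out
  } else {
    f(a, b)
  }
}

tree_map <- function(f, a) {
  if (is.list(a)) {
    out <- vector("list", length(a))
    names(out) <- names(a)
    for (i in seq_along(a)) out[[i]] <- tree_map(f, a[[i]])
    out
  } else {
    f(a)
  }
}

tree_flatten <- function(a) {
  if (is.list(a)) unlist(lapply(a, tree_flatten), use.names = FALSE)
  else as.numeric(a)
}

tree_unflatten <- function(skeleton, v) {
  i <- 0L
  rebuild <- function(a) {
    if (is.list(a)) {
      out <- vector("list", length(a))
      names(out) <- names(a)
      for (k in seq_along(a)) out[[k]] <- rebuild(a[[k]])
      out
    } else {
      n <- length(a)
      x <- v[(i + 1L):(i + n)]
      i <<- i + n
      if (!is.null(dim(a))) dim(x) <- dim(a)
      x
    }
  }
  out <- rebuild(skeleton)
  stopifnot(i == length(v))
  out
}
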