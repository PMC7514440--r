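# S3 methods for fitted nflmc samplers.

#' @export
print.nflmc <- function(x, ...) {
  cat("Langevin normalizing-flow sampler\n")
  cat("  target:    ", x$target$name, " (D = ", x$target$dim, ")\n", sep = "")
  cat("  flow:      ", x$config$n_layers, " layers, eps = ",
      format(x$config$epsilon), ", Ls = ", x$config$langevin_steps,
      ", conditioners ", paste(x$config$hidden, collapse = "x"), "\n", sep = "")
  cat("  training:  ", x$iterations, " iterations, batch ",
      x$config$batch_size, ", ", x$config$optimizer,
      " (rate ", format(x$config$learning_rate), ")\n", sep = "")
  cat("  gamma:     ", format(x$gamma), "\n", sep = "")
  if (length(x$loss_trace))
    cat("  final loss:", format(utils::tail(x$loss_trace, 1L)), "\n")
  if (isTRUE(x$diverged)) cat("  NOTE: training stopped early (non-finite loss)\n")
  invisible(x)
}

#' @export
summary.nflmc <- function(object, ...) {
  lt <- object$loss_trace
  out <- list(
    target = object$target$name, dim = object$target$dim,
    n_params = n_params(object$stack),
    iterations = object$iterations, gamma = object$gamma,
    loss_first = if (length(lt)) lt[1L] else NA_real_,
    loss_final = if (length(lt)) utils::tail(lt, 1L) else NA_real_,
    loss_min = if (length(lt)) min(lt) else NA_real_,
    config = object$config, diverged = object$diverged
  )
  class(out) <- "summary.nflmc"
  out
}

#' @export
print.summary.nflmc <- function(x, ...) {
  cat("nflmc fit on target '", x$target, "' (D = ", x$dim, ")\n", sep = "")
  cat("  trainable parameters:", x$n_params, "\n")
  cat("  iterations run:      ", x$iterations, "\n")
  cat("  gamma:               ", format(x$gamma), "\n")
  cat(sprintf("  loss: first %.4g, min %.4g, final %.4g\n",
              x$loss_first, x$loss_min, x$loss_final))
  invisible(x)
}

#' @export
coef.nflmc <- function(object, ...) tree_flatten(stack_params(object$stack))

#' Draw from a fitted sampler
#'
#' @param object a fitted [nflmc()] model.
#' @param nsim number of draws.
#' @param seed optional integer seed.
#' @param ... passed to [sample_flow()] (e.g. `log_prob = "forward"`).
#' @return a [sample_batch()].
#' @export
simulate.nflmc <- function(object, nsim = 1L, seed = NULL, ...) {
  sample_flow(object$stack, n = nsim, seed = seed, ...)
}

#' Plot a fitted sampler
#'
#' Loss trace on a log scale and, for two-dimensional targets, a scatter of
#' fresh draws.
#'
#' @param x a fitted [nflmc()] model.
#' @param n_draws draws for the scatter panel (2-D targets only).
#' @param seed seed for the scatter draws.
#' @param ... unused.
#' @export
plot.nflmc <- function(x, n_draws = 2000L, seed = 1L, ...) {
  two_d <- x$target$dim == 2L
  if (two_d) {
    op <- graphics::par(mfrow = c(1L, 2L))
    on.exit(graphics::par(op))
  }
  graphics::plot(seq_along(x$loss_trace), pmax(x$loss_trace, 1e-12),
                 type = "l", log = "y", xlab = "iteration", ylab = "loss",
                 main = "training loss")
  if (two_d) {
    b <- simulate(x, nsim = n_draws, seed = seed, log_prob = "forward")
    graphics::plot(b$points, pch = ".", cex = 2, xlab = "x1", ylab = "x2",
                   main = paste0("draws: ", x$target$name))
  }
  invisible(x)
}
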