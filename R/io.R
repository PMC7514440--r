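# Serialization: delimited-text sample files, structured-text checkpoints,
# YAML run configs and run manifests. Everything is plain text so runs are
# portable and diffable.

#' Write a sample batch to delimited text
#'
#' One row per draw: coordinate columns `x1..xD` plus `log_q_flow` and
#' `log_target_unnorm` when present, tab-separated with a header line.
#' `read_samples(write_samples(...))` reproduces the values exactly (values
#' are printed with full double precision).
#'
#' @param path writable file path.
#' @param batch a [sample_batch()] or a bare matrix of draws.
#' @return `path`, invisibly.
#' @export
write_samples <- function(path, batch) {
  df <- if (inherits(batch, "sample_batch")) as.data.frame(batch)
        else {
          M <- as.data.frame(as.matrix(batch))
          names(M) <- paste0("x", seq_len(ncol(M)))
          M
        }
  utils::write.table(format(df, digits = 17, scientific = TRUE, trim = TRUE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample file written by [write_samples()]
#'
#' @param path file path.
#' @return a [sample_batch()] when the log-density columns are present,
#'   otherwise a plain matrix of draws. Malformed files raise a parse error
#'   naming the offending line.
#' @export
read_samples <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 2L) stop("sample file has no data rows: ", path)
  header <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
  ncol <- length(header)
  rows <- strsplit(lines[-1L], "\t", fixed = TRUE)
  for (i in seq_along(rows)) {
    if (length(rows[[i]]) != ncol)
      stop("line ", i + 1L, ": expected ", ncol, " fields, found ",
           length(rows[[i]]))
    vals <- suppressWarnings(as.numeric(rows[[i]]))
    if (any(is.na(vals)))
      stop("line ", i + 1L, ": non-numeric value '",
           rows[[i]][which(is.na(vals))[1L]], "'")
  }
  M <- matrix(as.numeric(t(vapply(rows, as.numeric, numeric(ncol)))),
              ncol = ncol, byrow = FALSE,
              dimnames = list(NULL, header))
  xcols <- grep("^x[0-9]+$", header)
  if (all(c("log_q_flow", "log_target_unnorm") %in% header)) {
    sample_batch(M[, xcols, drop = FALSE], M[, "log_q_flow"],
                 M[, "log_target_unnorm"])
  } else {
    M[, xcols, drop = FALSE]
  }
}

#' Save / load flow parameters
#'
#' The checkpoint is a JSON document holding every conditioner weight at full
#' precision together with a sidecar header (epsilon, Langevin steps, layer
#' count, conditioner shapes, base distribution, target name, seed).
#' `read_checkpoint()` rebuilds the stack against a target; the catalog target
#' is looked up by name when none is supplied.
#'
#' @param stack a [flow_stack()].
#' @param path output path (JSON).
#' @param seed training seed to record.
#' @return `path`, invisibly.
#' @export
write_checkpoint <- function(stack, path, seed = NULL) {
  obj <- list(
    header = list(
      target = stack$target$name, dim = stack$target$dim,
      epsilon = stack$epsilon, langevin_steps = stack$langevin_steps,
      n_layers = length(stack$layers), hidden = stack$hidden,
      base_mean = stack$base$mean, base_scale = stack$base$scale,
      seed = seed),
    params = stack_params(stack)
  )
  # digits = I(17): %.17g round-trips doubles exactly through decimal text
  jsonlite::write_json(obj, path, digits = I(17), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_checkpoint
#' @param target a [target_distribution()] matching the checkpoint; defaults
#'   to the catalog entry named in the header.
#' @return `read_checkpoint()`: a [flow_stack()].
#' @export
read_checkpoint <- function(path, target = NULL) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  h <- obj$header
  if (is.null(target)) target <- get_target(h$target, dim = h$dim)
  stack <- flow_stack(target, n_layers = h$n_layers, epsilon = h$epsilon,
                      langevin_steps = h$langevin_steps, hidden = h$hidden,
                      base_mean = h$base_mean, base_scale = h$base_scale,
                      seed = 0L)
  # restore parameters (read_json returns matrices for the weight leaves)
  skel <- stack_params(stack)
  restore <- function(sk, pj) {
    if (is.list(sk)) {
      for (k in seq_along(sk)) sk[[k]] <- restore(sk[[k]], pj[[k]])
      sk
    } else {
      x <- as.numeric(unlist(pj))
      if (!is.null(dim(sk))) {
        m <- as.matrix(pj)
        storage.mode(m) <- "double"
        dimnames(m) <- NULL
        m
      } else x
    }
  }
  stack_set_params(stack, restore(skel, obj$params))
}

#' Read and validate a YAML run configuration
#'
#' Keys mirror the training inputs: `target` (catalog name, required),
#' `profile` (`test`/`paper`), `epsilon`, `langevin_steps` (Ls), `beta`
#' (learning rate), `gamma` (number or `"estimate"`), `k_iters`, `n` (batch
#' size), `n_layers`, `hidden`, `base_mean`, `base_scale`, `seed`,
#' `optimizer`.
#'
#' @param path YAML file.
#' @return validated named list of settings.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$target)) stop("config field 'target' is required")
  if (!is.null(cfg$gamma) && !identical(cfg$gamma, "estimate") &&
      (!is.numeric(cfg$gamma) || cfg$gamma <= 0))
    stop("config field 'gamma' must be a positive number or \"estimate\"")
  for (f in c("epsilon", "beta", "k_iters", "n", "n_layers",
              "langevin_steps", "seed"))
    if (!is.null(cfg[[f]]) && !is.numeric(cfg[[f]]))
      stop("config field '", f, "' must be numeric")
  cfg
}

#' Train from a config file and write run artifacts
#'
#' Runs the full training loop described by a YAML config and writes three
#' artifacts into `out_dir`: `checkpoint.json` (flow parameters + header),
#' `loss_trace.tsv` (iteration, loss) and `manifest.json` (config snapshot,
#' seed, package version, final loss, wall time, output paths) — enough to
#' reproduce the run bit for bit.
#'
#' @param config_path YAML config path (see [read_run_config()]).
#' @param out_dir output directory (created if missing).
#' @param verbose print progress.
#' @return the fitted [nflmc()] object, invisibly.
#' @export
run_train <- function(config_path, out_dir = ".", verbose = FALSE) {
  cfg <- read_run_config(config_path)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  target <- get_target(cfg$target, dim = cfg$dim %||% 2L)
  args <- list(target = target,
               profile = cfg$profile %||% "test",
               gamma = cfg$gamma %||% "auto",
               seed = as.integer(cfg$seed %||% 1L),
               verbose = verbose)
  opt_map <- c(epsilon = "epsilon", langevin_steps = "langevin_steps",
               beta = "learning_rate", k_iters = "iterations",
               n = "batch_size", n_layers = "n_layers", hidden = "hidden",
               base_mean = "base_mean", base_scale = "base_scale",
               optimizer = "optimizer")
  for (k in names(opt_map))
    if (!is.null(cfg[[k]])) args[[opt_map[[k]]]] <- cfg[[k]]
  t0 <- proc.time()[["elapsed"]]
  fit <- do.call(nflmc, args)
  wall <- proc.time()[["elapsed"]] - t0
  ck <- file.path(out_dir, "checkpoint.json")
  tr <- file.path(out_dir, "loss_trace.tsv")
  mf <- file.path(out_dir, "manifest.json")
  write_checkpoint(fit$stack, ck, seed = fit$config$seed)
  utils::write.table(
    data.frame(iteration = seq_along(fit$loss_trace), loss = fit$loss_trace),
    tr, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(
    config = cfg, resolved = fit$config, seed = fit$config$seed,
    package_version = as.character(utils::packageVersion("nflmc")),
    final_loss = utils::tail(fit$loss_trace, 1L),
    gamma = fit$gamma, wall_time_s = wall,
    outputs = list(checkpoint = ck, loss_trace = tr, manifest = mf)),
    mf, digits = NA, auto_unbox = TRUE)
  invisible(fit)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
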