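# Model construction and inference for the multi-scale fusion attention
# U-Net.  A built network is a list of (config, parameter environment,
# batch-norm running statistics); the forward pass re-runs the architecture
# on a fresh tape each call.

#' Architecture hyperparameters
#'
#' @param in_channels input image channels (CT slices are single-channel).
#' @param num_levels number of resolution branches / encoder levels (>= 2).
#'   Branch `i` runs at `1 / 2^(i-1)` of the input resolution.
#' @param base_channels channel width of the highest-resolution branch;
#'   widths double per level.  Must be even and at least `cse_reduction`.
#' @param cse_reduction channel-halving factor inside the cSE attention
#'   bottleneck (2: the bottleneck has half the channels).
#' @param dropout_rate dropout probability applied after each decoder skip
#'   concatenation (default 0.2).
#' @param out_channels output channels (1: sigmoid foreground probability).
#' @return A validated `model_config` list.
#' @export
model_config <- function(in_channels = 1L, num_levels = 4L,
                         base_channels = 32L, cse_reduction = 2L,
                         dropout_rate = 0.2, out_channels = 1L) {
  cfg <- list(in_channels = as.integer(in_channels),
              num_levels = as.integer(num_levels),
              base_channels = as.integer(base_channels),
              cse_reduction = as.integer(cse_reduction),
              dropout_rate = dropout_rate,
              out_channels = as.integer(out_channels))
  if (cfg$num_levels < 2L) stop("num_levels must be >= 2")
  if (cfg$base_channels %% 2L != 0L || cfg$base_channels < cfg$cse_reduction)
    stop("base_channels must be even and >= cse_reduction")
  if (cfg$dropout_rate < 0 || cfg$dropout_rate >= 1)
    stop("dropout_rate must be in [0, 1)")
  class(cfg) <- "model_config"
  cfg
}

#' Build a multi-scale fusion attention U-Net
#'
#' Instantiates all network parameters (He-uniform convolution weights, zero
#' biases, unit-gamma/zero-beta batch norms) by tracing the architecture
#' once on a dummy input.
#'
#' @param config a [model_config()].
#' @param seed RNG seed for weight initialization.
#' @return An object of class `msfa_net` with elements `config`, `params`
#'   (environment of named arrays) and `bn_state` (running statistics).
#' @export
build_model <- function(config = model_config(), seed = 1L) {
  if (!inherits(config, "model_config")) config <- do.call(model_config, config)
  net <- list(config = config,
              params = new.env(parent = emptyenv()),
              bn_state = new.env(parent = emptyenv()))
  class(net) <- "msfa_net"
  old <- .save_rng()
  on.exit(.restore_rng(old), add = TRUE)
  set.seed(seed)
  s <- 2L^(config$num_levels - 1L) * 2L
  dummy <- array(0, c(config$in_channels, s, s, 1L))
  ctx <- new_ctx(params = net$params, bn_state = net$bn_state,
                 training = FALSE, init = TRUE)
  arch_forward(ctx, op_input(ctx, dummy), config)
  net
}

#' Number of trainable parameters
#' @param net an `msfa_net`.
#' @export
n_parameters <- function(net) {
  sum(vapply(ls(net$params), function(nm)
    length(get(nm, envir = net$params)), numeric(1)))
}

check_input_size <- function(config, h, w) {
  div <- 2L^(config$num_levels - 1L)
  if (h %% div != 0L || w %% div != 0L)
    stop("input spatial size ", h, "x", w, " must be divisible by 2^",
         config$num_levels - 1L, " = ", div)
}

# Coerce user input (H x W matrix, H x W x N array, list of matrices, or a
# (C, H, W, N) array) to the internal channel-first batch layout.
as_image_batch <- function(images, in_channels = 1L) {
  if (is.list(images)) {
    d <- dim(images[[1]])
    x <- array(0, c(in_channels, d[1], d[2], length(images)))
    for (i in seq_along(images)) x[1, , , i] <- images[[i]]
    return(x)
  }
  d <- dim(images)
  if (length(d) == 2L) return(array(images, c(1L, d, 1L)))
  if (length(d) == 3L) {                    # H x W x N
    x <- array(0, c(1L, d))
    x[1, , , ] <- images
    return(x)
  }
  if (length(d) == 4L) return(images)
  stop("unrecognized image input")
}

#' Network forward pass
#'
#' Runs a batch of normalized images through the network and returns
#' per-pixel foreground probabilities.  In inference mode (the default) the
#' pass is deterministic: dropout is disabled and batch normalization uses
#' running statistics, so samples in a batch do not interact.
#'
#' @param net an `msfa_net` from [build_model()].
#' @param images `H x W` matrix, `H x W x N` array, list of matrices, or a
#'   channel-first `(C, H, W, N)` array; values are expected in `[0, 1]`.
#'   `H` and `W` must be divisible by `2^(num_levels - 1)`.
#' @param training logical; `TRUE` enables dropout and batch-statistic
#'   normalization (used internally by the trainer).
#' @return `(1, H, W, N)` array of probabilities in `(0, 1)`.
#' @export
msfa_forward <- function(net, images, training = FALSE) {
  x <- as_image_batch(images, net$config$in_channels)
  d <- dim(x)
  check_input_size(net$config, d[2], d[3])
  ctx <- new_ctx(params = net$params, bn_state = net$bn_state,
                 training = training, init = FALSE)
  out_id <- arch_forward(ctx, op_input(ctx, x), net$config)
  node_val(ctx, out_id)
}

# Forward + Dice-loss backward in one tape; returns loss, output and
# parameter gradients.  Used by the trainer.
msfa_forward_backward <- function(net, images, masks, eps = 1) {
  x <- as_image_batch(images, net$config$in_channels)
  t <- as_image_batch(masks, 1L)
  d <- dim(x)
  check_input_size(net$config, d[2], d[3])
  ctx <- new_ctx(params = net$params, bn_state = net$bn_state,
                 training = TRUE, init = FALSE)
  out_id <- arch_forward(ctx, op_input(ctx, x), net$config)
  p <- node_val(ctx, out_id)
  dl <- dice_loss_grad(p, t, eps)
  grads <- tape_backward(ctx, out_id, dl$grad)
  list(loss = dl$loss, pred = p, grads = grads)
}

#' @export
print.msfa_net <- function(x, ...) {
  cfg <- x$config
  cat("Multi-scale fusion attention U-Net\n")
  cat(sprintf("  levels: %d  widths: %s  dropout: %.2f\n", cfg$num_levels,
              paste(cfg$base_channels * 2^(seq_len(cfg$num_levels) - 1),
                    collapse = "/"),
              cfg$dropout_rate))
  cat(sprintf("  parameters: %s\n", format(n_parameters(x), big.mark = ",")))
  invisible(x)
}

# ---- checkpointing --------------------------------------------------------

#' Save / load a network checkpoint
#'
#' The checkpoint is a single RDS file holding parameters, batch-norm
#' running statistics and the architecture configuration; the configuration
#' is also written alongside as JSON (`<path>.json`) so checkpoints are
#' self-describing.
#'
#' @param net an `msfa_net` (or fitted `msfa_unet`; its network is saved).
#' @param path file path for the checkpoint.
#' @export
save_checkpoint <- function(net, path) {
  if (inherits(net, "msfa_unet")) net <- net$net
  obj <- list(config = unclass(net$config),
              params = as.list(net$params),
              bn_state = as.list(net$bn_state))
  saveRDS(obj, path)
  jsonlite::write_json(unclass(net$config), paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  net <- list(config = do.call(model_config, obj$config),
              params = list2env(obj$params, parent = emptyenv()),
              bn_state = list2env(obj$bn_state, parent = emptyenv()))
  class(net) <- "msfa_net"
  net
}
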