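# Network building blocks: cSE channel attention, attention residual block,
# stride-convolution / transposed-convolution scale transitions, and
# multi-scale fusion.  Each block is expressed in tape ops (autodiff.R) so
# the same code path serves initialization, training and inference.

# cSE: global average pool -> bottleneck dense (C -> C/r, ReLU) ->
# dense (C/r -> C, sigmoid gate) -> channel-wise multiplication.
ly_cse <- function(ctx, xid, name, reduction = 2L) {
  C <- dim(node_val(ctx, xid))[1]
  mid <- max(1L, C %/% reduction)
  v <- op_gap(ctx, xid)
  v <- op_dense(ctx, v, paste0(name, ".squeeze"), mid)
  v <- op_relu(ctx, v)
  v <- op_dense(ctx, v, paste0(name, ".excite"), C)
  s <- op_sigmoid(ctx, v)
  op_scale_ch(ctx, xid, s)
}

# Attention residual block: main path conv3x3 -> BN -> ReLU -> conv3x3 -> BN
# -> cSE, plus projection shortcut conv1x1 -> BN; outputs their sum.
ly_resblock <- function(ctx, xid, name, width, reduction = 2L) {
  m <- op_conv(ctx, xid, paste0(name, ".conv1"), width, k = 3L)
  m <- op_bn(ctx, m, paste0(name, ".bn1"))
  m <- op_relu(ctx, m)
  m <- op_conv(ctx, m, paste0(name, ".conv2"), width, k = 3L)
  m <- op_bn(ctx, m, paste0(name, ".bn2"))
  m <- ly_cse(ctx, m, paste0(name, ".cse"), reduction)
  s <- op_conv(ctx, xid, paste0(name, ".proj"), width, k = 1L)
  s <- op_bn(ctx, s, paste0(name, ".projbn"))
  op_add(ctx, m, s)
}

# High-to-low transition: `steps` chained 3x3 stride-2 convolutions
# (BN after each, ReLU between chained steps), halving H and W each step.
ly_down <- function(ctx, xid, name, steps, width) {
  stopifnot(steps >= 1L)
  h <- xid
  for (s in seq_len(steps)) {
    d <- dim(node_val(ctx, h))
    if (d[2] %% 2L != 0L || d[3] %% 2L != 0L)
      stop("downscale: spatial dims ", d[2], "x", d[3], " not divisible by 2")
    h <- op_conv(ctx, h, sprintf("%s.conv%d", name, s), width,
                 k = 3L, stride = 2L)
    h <- op_bn(ctx, h, sprintf("%s.bn%d", name, s))
    if (s < steps) h <- op_relu(ctx, h)
  }
  h
}

# Low-to-high transition: `steps` chained 3x3 stride-2 transposed
# convolutions, doubling H and W each step.
ly_up <- function(ctx, xid, name, steps, width) {
  stopifnot(steps >= 1L)
  h <- xid
  for (s in seq_len(steps)) {
    h <- op_convt(ctx, h, sprintf("%s.conv%d", name, s), width)
    h <- op_bn(ctx, h, sprintf("%s.bn%d", name, s))
    if (s < steps) h <- op_relu(ctx, h)
  }
  h
}

# Multi-scale fusion: for each active branch i, sum identity (j = i),
# downscale (j < i) and upscale (j > i) transitions of every branch j,
# then ReLU.  Branch i lives at resolution full / 2^(i-1) with width[i]
# channels; shapes per branch are preserved.
ly_fuse <- function(ctx, branch_ids, name, widths) {
  k <- length(branch_ids)
  out <- integer(k)
  for (i in seq_len(k)) {
    acc <- NULL
    for (j in seq_len(k)) {
      term <- if (j == i) {
        branch_ids[j]
      } else if (j < i) {
        ly_down(ctx, branch_ids[j], sprintf("%s.d%dto%d", name, j, i),
                i - j, widths[i])
      } else {
        ly_up(ctx, branch_ids[j], sprintf("%s.u%dto%d", name, j, i),
              j - i, widths[i])
      }
      acc <- if (is.null(acc)) term else op_add(ctx, acc, term)
    }
    out[i] <- if (k > 1) op_relu(ctx, acc) else acc
  }
  out
}

# Whole-network forward: HRNet-style encoder (stage k runs branches 1..k
# through attention resblocks then fuses across scales, and spawns the next
# lower-resolution branch), U-Net-style decoder (transposed-conv upsampling,
# skip concatenation with post-fusion encoder features, dropout after each
# skip, attention resblock), 1x1 conv + sigmoid head.
arch_forward <- function(ctx, xid, config) {
  L <- config$num_levels
  w <- config$base_channels * 2^(seq_len(L) - 1)
  br <- integer(L)
  br[1] <- xid
  for (stage in seq_len(L)) {
    act <- seq_len(stage)
    for (i in act)
      br[i] <- ly_resblock(ctx, br[i], sprintf("enc.s%d.b%d", stage, i),
                           w[i], config$cse_reduction)
    br[act] <- ly_fuse(ctx, br[act], sprintf("enc.s%d.fuse", stage), w)
    if (stage < L)
      br[stage + 1] <- ly_down(ctx, br[stage], sprintf("enc.s%d.spawn", stage),
                               1L, w[stage + 1])
  }
  d <- br[L]
  for (i in rev(seq_len(L - 1))) {
    u <- op_convt(ctx, d, sprintf("dec.l%d.up", i), w[i])
    u <- op_bn(ctx, u, sprintf("dec.l%d.upbn", i))
    u <- op_relu(ctx, u)
    cat_id <- op_concat(ctx, u, br[i])
    cat_id <- op_dropout(ctx, cat_id, config$dropout_rate)
    d <- ly_resblock(ctx, cat_id, sprintf("dec.l%d.res", i), w[i],
                     config$cse_reduction)
  }
  h <- op_conv(ctx, d, "head", config$out_channels, k = 1L)
  op_sigmoid(ctx, h)
}

# ---- Functional wrappers for the individual blocks ------------------------
# Each wrapper runs the corresponding block on a standalone parameter set
# (freshly He-initialized from `seed` when `params` is NULL), with batch
# normalization in inference mode and identity running statistics.  The
# parameter set actually used is attached as attribute "params" so callers
# can inspect or override it.

run_block <- function(fm, params, seed, fn) {
  init <- is.null(params)
  penv <- new.env(parent = emptyenv())
  if (!init) for (nm in names(params)) assign(nm, params[[nm]], envir = penv)
  ctx <- new_ctx(params = penv, training = FALSE, init = init)
  out_id <- if (init) {
    withr_seed <- .save_rng()
    on.exit(.restore_rng(withr_seed), add = TRUE)
    set.seed(seed)
    fn(ctx, op_input(ctx, as_batch(fm)))
  } else {
    fn(ctx, op_input(ctx, as_batch(fm)))
  }
  out <- node_val(ctx, out_id)
  if (length(dim(fm)) < 4L) out <- array(out, dim(out)[1:3])
  structure(out, params = as.list(penv))
}

.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.restore_rng <- function(s) {
  if (is.null(s)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", s, envir = globalenv())
}

#' Channel squeeze-and-excitation recalibration
#'
#' Applies a cSE gate to a channel-first feature map: each channel is
#' average-pooled to a scalar, pushed through a two-layer bottleneck whose
#' hidden width is `C / reduction` (ReLU inside, sigmoid out), and the
#' resulting per-channel gate in (0, 1) rescales the input channels.
#'
#' @param fm numeric array, `(C, H, W)` or `(C, H, W, N)`, channel-first.
#' @param params optional named list of block weights (as returned in the
#'   `"params"` attribute of a previous call); when `NULL`, weights are
#'   He-initialized from `seed`.
#' @param reduction integer channel-halving factor of the bottleneck
#'   (default 2: the hidden layer has `C / 2` units).
#' @param seed RNG seed for weight initialization.
#' @return The recalibrated feature map, same shape as `fm`, with the
#'   parameter list attached as attribute `"params"`.
#' @examples
#' fm <- array(rnorm(4 * 8 * 8), c(4, 8, 8))
#' out <- cse_recalibrate(fm)
#' stopifnot(all(abs(out) <= abs(fm) + 1e-12))
#' @export
cse_recalibrate <- function(fm, params = NULL, reduction = 2L, seed = 1L) {
  run_block(fm, params, seed,
            function(ctx, xid) ly_cse(ctx, xid, "op", reduction))
}

#' Attention residual block
#'
#' Two 3x3 convolutions (each followed by batch normalization, ReLU after
#' the first) ending in a cSE attention gate, summed with a projection
#' shortcut (1x1 convolution + batch normalization).  Spatial size is
#' preserved; output channel count is `width`.
#'
#' @inheritParams cse_recalibrate
#' @param width output channel count of the block.
#' @return Feature map of shape `(width, H, W[, N])` with attribute
#'   `"params"`.
#' @export
attention_resblock <- function(fm, width, params = NULL, reduction = 2L,
                               seed = 1L) {
  run_block(fm, params, seed,
            function(ctx, xid) ly_resblock(ctx, xid, "op", width, reduction))
}

#' High-to-low resolution transition
#'
#' `levels_down` chained 3x3 stride-2 convolutions (batch normalization
#' after each, ReLU between steps); each step halves height and width.
#'
#' @inheritParams attention_resblock
#' @param levels_down number of resolution levels to descend (>= 1).
#' @export
downscale_transition <- function(fm, levels_down, width, params = NULL,
                                 seed = 1L) {
  if (levels_down < 1L)
    stop("levels_down must be >= 1; use the identity path for 0")
  run_block(fm, params, seed,
            function(ctx, xid) ly_down(ctx, xid, "op", levels_down, width))
}

#' Low-to-high resolution transition
#'
#' `levels_up` chained 3x3 stride-2 transposed convolutions (batch
#' normalization after each, ReLU between steps); each step doubles height
#' and width exactly.
#'
#' @inheritParams attention_resblock
#' @param levels_up number of resolution levels to ascend (>= 1).
#' @export
upscale_transition <- function(fm, levels_up, width, params = NULL,
                               seed = 1L) {
  if (levels_up < 1L)
    stop("levels_up must be >= 1; use the identity path for 0")
  run_block(fm, params, seed,
            function(ctx, xid) ly_up(ctx, xid, "op", levels_up, width))
}

#' Multi-scale feature fusion
#'
#' Fuses a list of per-branch feature maps, where branch `i` lives at
#' resolution `full / 2^(i-1)`.  The fused output for branch `i` is the
#' elementwise sum over all branches `j` of a transition of branch `j` to
#' resolution `i` (identity for `j == i`, chained stride-2 convolutions for
#' `j < i`, chained transposed convolutions for `j > i`), followed by ReLU.
#' Per-branch shapes are unchanged.
#'
#' @param branch_fms list of channel-first feature maps, highest resolution
#'   first; branch `i` must have `widths[i]` channels and spatial dims
#'   `full / 2^(i-1)`.
#' @param widths integer vector of channel widths per branch.
#' @inheritParams cse_recalibrate
#' @return List of fused feature maps (same shapes as input), with
#'   attribute `"params"`.
#' @export
multi_scale_fuse <- function(branch_fms, widths, params = NULL, seed = 1L) {
  stopifnot(is.list(branch_fms), length(widths) == length(branch_fms))
  k <- length(branch_fms)
  d1 <- dim(as_batch(branch_fms[[1]]))
  for (i in seq_len(k)) {
    di <- dim(as_batch(branch_fms[[i]]))
    if (di[1] != widths[i] || di[2] * 2^(i - 1) != d1[2] ||
        di[3] * 2^(i - 1) != d1[3])
      stop("branch ", i, " has inconsistent shape for its resolution level")
  }
  init <- is.null(params)
  penv <- new.env(parent = emptyenv())
  if (!init) for (nm in names(params)) assign(nm, params[[nm]], envir = penv)
  ctx <- new_ctx(params = penv, training = FALSE, init = init)
  if (init) {
    old <- .save_rng()
    on.exit(.restore_rng(old), add = TRUE)
    set.seed(seed)
  }
  ids <- vapply(branch_fms, function(f) op_input(ctx, as_batch(f)), integer(1))
  out_ids <- ly_fuse(ctx, ids, "op", widths)
  out <- lapply(seq_len(k), function(i) {
    v <- node_val(ctx, out_ids[i])
    if (length(dim(branch_fms[[i]])) < 4L) v <- array(v, dim(v)[1:3])
    v
  })
  structure(out, params = as.list(penv))
}
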