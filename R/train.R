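# Training: Adam optimization of the Dice loss with staircase exponential
# learning-rate decay, on-the-fly augmentation, per-epoch validation and
# best-validation checkpointing.  `msfa_train()` is the fitting function;
# it returns a classed object with predict/print/summary/plot/coef
# methods.

#' Training configuration
#'
#' Defaults follow the reference operating point for this architecture:
#' batch size 2, 120 epochs, 512x512 inputs, initial learning rate 2e-4
#' with staircase exponential decay (rate 0.96 every 300 optimizer steps).
#'
#' @param batch_size mini-batch size (>= 1).
#' @param epochs number of passes over the training split (>= 1).
#' @param image_size expected square input size; inputs are validated
#'   against the model's divisibility constraint.
#' @param initial_lr initial learning rate.
#' @param decay_steps optimizer steps between decay applications.
#' @param decay_rate multiplicative decay coefficient in (0, 1].
#' @param optimizer `"adam"` (default) or `"sgd"`.
#' @param eps Dice-loss smoothing constant.
#' @param seed RNG seed covering weight init, shuffling, augmentation and
#'   dropout.
#' @param model a [model_config()].
#' @param window a [window_spec()] applied to HU inputs.
#' @param clahe logical, apply adaptive histogram equalization after
#'   windowing.
#' @param clahe_tiles tile grid for the equalizer.
#' @param augment logical, sample one random rotation/flip/zoom/shear
#'   transform per training image per epoch.
#' @param threshold probability threshold for binarizing predictions.
#' @return A validated `train_config` list.
#' @export
train_config <- function(batch_size = 2L, epochs = 120L, image_size = 512L,
                         initial_lr = 2e-4, decay_steps = 300L,
                         decay_rate = 0.96, optimizer = c("adam", "sgd"),
                         eps = 1, seed = 1L, model = model_config(),
                         window = window_spec(), clahe = TRUE,
                         clahe_tiles = c(8L, 8L), augment = TRUE,
                         threshold = 0.5) {
  optimizer <- match.arg(optimizer)
  cfg <- list(batch_size = as.integer(batch_size),
              epochs = as.integer(epochs),
              image_size = as.integer(image_size),
              initial_lr = initial_lr, decay_steps = as.integer(decay_steps),
              decay_rate = decay_rate, optimizer = optimizer, eps = eps,
              seed = as.integer(seed), model = model, window = window,
              clahe = clahe, clahe_tiles = as.integer(clahe_tiles),
              augment = augment, threshold = threshold)
  if (cfg$batch_size < 1L) stop("batch_size must be >= 1")
  if (cfg$epochs < 1L) stop("epochs must be >= 1")
  if (cfg$decay_rate <= 0 || cfg$decay_rate > 1)
    stop("decay_rate must be in (0, 1]")
  class(cfg) <- "train_config"
  cfg
}

#' Staircase exponential learning-rate schedule
#'
#' `lr(step) = initial_lr * decay_rate ^ floor(step / decay_steps)`, where
#' a step is one optimizer iteration.  Nonincreasing in `step`.
#'
#' @param step optimizer iteration (>= 0).
#' @param cfg a [train_config()] (or any list with `initial_lr`,
#'   `decay_rate`, `decay_steps`).
#' @return The learning rate at `step`.
#' @export
lr_schedule <- function(step, cfg = train_config()) {
  stopifnot(all(step >= 0))
  cfg$initial_lr * cfg$decay_rate^(step %/% cfg$decay_steps)
}

# Optimizer state: step count plus first/second moment accumulators,
# held in an environment so updates persist across calls.
new_optimizer <- function() {
  e <- new.env(parent = emptyenv())
  e$t <- 0
  e$m <- new.env(parent = emptyenv())
  e$v <- new.env(parent = emptyenv())
  e
}

adam_update <- function(params, grads, opt, lr,
                        beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  opt$t <- opt$t + 1
  corr1 <- 1 - beta1^opt$t
  corr2 <- 1 - beta2^opt$t
  for (nm in ls(grads)) {
    g <- get(nm, envir = grads, inherits = FALSE)
    m <- if (exists(nm, envir = opt$m, inherits = FALSE))
      get(nm, envir = opt$m) else 0
    v <- if (exists(nm, envir = opt$v, inherits = FALSE))
      get(nm, envir = opt$v) else 0
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g * g
    assign(nm, m, envir = opt$m)
    assign(nm, v, envir = opt$v)
    p <- get(nm, envir = params, inherits = FALSE)
    assign(nm, p - lr * (m / corr1) / (sqrt(v / corr2) + eps), envir = params)
  }
}

sgd_update <- function(params, grads, lr) {
  for (nm in ls(grads)) {
    p <- get(nm, envir = params, inherits = FALSE)
    assign(nm, p - lr * get(nm, envir = grads, inherits = FALSE),
           envir = params)
  }
}

# Preprocess one HU image to the model's [0,1] input space.
preprocess_hu <- function(hu, cfg) {
  x <- apply_window(hu, cfg$window)
  if (isTRUE(cfg$clahe)) x <- adaptive_hist_equalize(x, cfg$clahe_tiles)
  x
}

# Load a manifest (data frame or CSV path) into in-memory HU images/masks.
load_manifest <- function(manifest) {
  if (is.character(manifest)) manifest <- utils::read.csv(manifest)
  stopifnot(all(c("case_id", "image_path", "mask_path") %in% names(manifest)))
  images <- lapply(manifest$image_path, read_hu_slice)
  masks <- lapply(manifest$mask_path, read_mask_png)
  list(manifest = manifest, images = images, masks = masks)
}

#' Fit the segmentation network
#'
#' Trains the multi-scale fusion attention U-Net on the training split by
#' mini-batch optimization of the Dice loss, with on-the-fly augmentation,
#' per-epoch validation Dice monitoring, and best-validation weight
#' selection.  Fully deterministic for a fixed config and seed.
#'
#' @param data either a manifest (data frame or CSV path with columns
#'   `case_id`, `image_path`, `mask_path`, `split`) or a list with
#'   elements `images` (list of HU matrices), `masks` (list of 0/1
#'   matrices) and `split` (character vector `"train"` /
#'   `"validation"` / `"test"` per case).  Images referenced by a manifest
#'   are DICOM slices.
#' @param config a [train_config()].
#' @param verbose print a line per epoch.
#' @return An object of class `msfa_unet`: the fitted network (best
#'   validation weights), the configuration, and a per-epoch history of
#'   train loss, validation loss, validation DSC and learning rate.
#' @export
msfa_train <- function(data, config = train_config(), verbose = FALSE) {
  cl <- match.call()
  if (is.character(data) || is.data.frame(data)) {
    loaded <- load_manifest(data)
    if (is.null(loaded$manifest$split))
      stop("manifest must carry a 'split' column")
    data <- list(images = loaded$images, masks = loaded$masks,
                 split = loaded$manifest$split)
  }
  split <- data$split
  tr <- which(split == "train")
  va <- which(split == "validation")
  if (length(tr) == 0L) stop("empty training split")
  imgs <- lapply(data$images, preprocess_hu, cfg = config)
  masks <- data$masks

  old <- .save_rng()
  on.exit(.restore_rng(old), add = TRUE)
  set.seed(config$seed)
  net <- build_model(config$model, seed = config$seed)

  opt <- new_optimizer()
  step <- 0L
  best <- list(dsc = -Inf, params = NULL, bn = NULL, epoch = NA_integer_)
  hist <- data.frame(epoch = integer(), train_loss = numeric(),
                     val_loss = numeric(), val_dsc = numeric(),
                     lr = numeric())

  for (epoch in seq_len(config$epochs)) {
    ord <- sample(tr)
    ep_loss <- 0
    nb <- 0L
    for (s in seq(1L, length(ord), by = config$batch_size)) {
      idx <- ord[s:min(s + config$batch_size - 1L, length(ord))]
      bi <- vector("list", length(idx))
      bm <- vector("list", length(idx))
      for (k in seq_along(idx)) {
        if (isTRUE(config$augment)) {
          aug <- augment_pair(imgs[[idx[k]]], masks[[idx[k]]],
                              sample_augment_spec())
          bi[[k]] <- aug$img
          bm[[k]] <- aug$mask
        } else {
          bi[[k]] <- imgs[[idx[k]]]
          bm[[k]] <- masks[[idx[k]]]
        }
      }
      lr <- lr_schedule(step, config)
      fb <- msfa_forward_backward(net, bi, bm, eps = config$eps)
      if (!is.finite(fb$loss))
        stop("non-finite training loss at step ", step, "; aborting")
      if (config$optimizer == "adam")
        adam_update(net$params, fb$grads, opt, lr)
      else sgd_update(net$params, fb$grads, lr)
      step <- step + 1L
      ep_loss <- ep_loss + fb$loss
      nb <- nb + 1L
    }
    ep_loss <- ep_loss / nb

    val <- eval_on_indices(net, imgs, masks, va, config)
    hist <- rbind(hist, data.frame(epoch = epoch, train_loss = ep_loss,
                                   val_loss = val$loss, val_dsc = val$dsc,
                                   lr = lr_schedule(step - 1L, config)))
    if (verbose)
      message(sprintf("epoch %3d  train loss %.4f  val loss %.4f  val DSC %.4f",
                      epoch, ep_loss, val$loss, val$dsc))
    if (is.na(val$dsc) || val$dsc >= best$dsc) {
      best <- list(dsc = val$dsc, params = as.list(net$params),
                   bn = as.list(net$bn_state), epoch = epoch)
    }
  }

  if (!is.null(best$params)) {
    net$params <- list2env(best$params, parent = emptyenv())
    net$bn_state <- list2env(best$bn, parent = emptyenv())
  }
  structure(list(net = net, config = config, history = hist,
                 best_epoch = best$epoch, call = cl),
            class = "msfa_unet")
}

# Validation helper: loss + mean DSC over the given case indices.
eval_on_indices <- function(net, imgs, masks, idx, config) {
  if (length(idx) == 0L) return(list(loss = NA_real_, dsc = NA_real_))
  losses <- numeric(length(idx))
  dscs <- numeric(length(idx))
  for (k in seq_along(idx)) {
    p <- msfa_forward(net, imgs[[idx[k]]])[1, , , 1]
    losses[k] <- dice_loss(p, masks[[idx[k]]], eps = config$eps)
    pred <- (p >= config$threshold) * 1
    dscs[k] <- overlap_metrics(confusion_counts(pred, masks[[idx[k]]]))["dsc"]
  }
  list(loss = mean(losses), dsc = mean(dscs))
}

#' Predict segmentation masks
#'
#' Applies the fitted model's preprocessing (window/level, optional
#' adaptive histogram equalization) to HU-valued inputs, runs the network
#' in inference mode and (by default) binarizes the probability maps at
#' the configured threshold.
#'
#' @param object a fitted `msfa_unet`.
#' @param newdata HU image matrix, list of matrices, or a manifest data
#'   frame / CSV path with an `image_path` column of DICOM slices.
#' @param type `"mask"` (binary, default) or `"prob"` (probability maps).
#' @param threshold binarization threshold (default from the training
#'   config).
#' @param ... unused.
#' @return List of predicted matrices (single input: still a list of 1).
#' @export
predict.msfa_unet <- function(object, newdata, type = c("mask", "prob"),
                              threshold = NULL, ...) {
  type <- match.arg(type)
  if (is.null(threshold)) threshold <- object$config$threshold
  if (is.character(newdata)) newdata <- utils::read.csv(newdata)
  if (is.data.frame(newdata))
    newdata <- lapply(newdata$image_path, read_hu_slice)
  if (is.matrix(newdata)) newdata <- list(newdata)
  lapply(newdata, function(hu) {
    x <- preprocess_hu(hu, object$config)
    p <- msfa_forward(object$net, x)[1, , , 1]
    if (type == "prob") p else (p >= threshold) * 1
  })
}

#' @export
print.msfa_unet <- function(x, ...) {
  cat("Fitted multi-scale fusion attention U-Net\n")
  print(x$net)
  h <- x$history
  if (nrow(h)) {
    last <- h[nrow(h), ]
    cat(sprintf("  epochs: %d  final train loss: %.4f  best val DSC: %.4f (epoch %s)\n",
                nrow(h), last$train_loss,
                suppressWarnings(max(h$val_dsc, na.rm = TRUE)),
                x$best_epoch))
  }
  invisible(x)
}

#' @export
summary.msfa_unet <- function(object, ...) {
  structure(list(config = object$config, history = object$history,
                 n_par = n_parameters(object$net),
                 best_epoch = object$best_epoch), class = "summary.msfa_unet")
}

#' @export
print.summary.msfa_unet <- function(x, ...) {
  cat("Multi-scale fusion attention U-Net fit\n")
  cat(sprintf("  parameters: %s   best epoch: %s\n",
              format(x$n_par, big.mark = ","), x$best_epoch))
  cat(sprintf("  batch %d, %d epochs, lr %.2e (decay %.2f / %d steps, staircase)\n",
              x$config$batch_size, x$config$epochs, x$config$initial_lr,
              x$config$decay_rate, x$config$decay_steps))
  cat("training history (last 5 epochs):\n")
  print(utils::tail(x$history, 5), row.names = FALSE)
  invisible(x)
}

#' @export
coef.msfa_unet <- function(object, ...) as.list(object$net$params)

#' Plot training curves
#'
#' Train/validation Dice loss per epoch, with validation DSC on a second
#' axis.
#' @param x a fitted `msfa_unet`; @param ... passed to `matplot`.
#' @export
plot.msfa_unet <- function(x, ...) {
  h <- x$history
  graphics::matplot(h$epoch, cbind(h$train_loss, h$val_loss), type = "l",
                    lty = 1, col = c("black", "red3"),
                    xlab = "epoch", ylab = "Dice loss", ...)
  graphics::legend("topright", c("train", "validation"), lty = 1,
                   col = c("black", "red3"), bty = "n")
  invisible(x)
}
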