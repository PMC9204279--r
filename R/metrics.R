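# Training loss and evaluation indices for binary segmentation.
#
# The loss is the smoothed soft Dice loss
#   DL = 1 - (2 * sum(p * t) + eps) / (sum p + sum t + eps),
# averaged over the samples of a batch.  Evaluation uses the exact
# binarized indices DSC, JSC, PPV, SE and the exact (maximum, not
# percentile) symmetric Hausdorff distance between foreground point sets.

#' Soft Dice loss
#'
#' Class-imbalance-robust overlap loss for small structures such as the
#' thyroid: `1 - (2 * sum(pred * target) + eps) / (sum(pred) + sum(target)
#' + eps)`, averaged over batch samples.  Differentiable in `pred`; for a
#' perfect binary prediction the loss is exactly 0, and for `eps > 0` it is
#' always in `[0, 1)`.
#'
#' @param pred probability map(s) in `[0, 1]`; matrix, `(H, W, N)` or
#'   channel-first `(1, H, W, N)` array.
#' @param target binary mask(s), same shape.
#' @param eps smoothing constant avoiding division by zero (default 1, the
#'   usual V-Net-style choice).
#' @return Scalar loss.
#' @export
dice_loss <- function(pred, target, eps = 1) {
  if (eps <= 0) stop("eps must be > 0")
  p <- as_image_batch(pred)
  t <- as_image_batch(target)
  if (!identical(dim(p), dim(t))) stop("pred and target shapes differ")
  dice_loss_grad(p, t, eps)$loss
}

# Loss plus gradient with respect to pred, both computed per sample and
# averaged; used by the trainer to seed backpropagation.
dice_loss_grad <- function(p, t, eps = 1) {
  n <- dim(p)[4]
  loss <- 0
  grad <- array(0, dim(p))
  for (i in seq_len(n)) {
    pi <- p[, , , i]
    ti <- t[, , , i]
    I <- sum(pi * ti)
    P <- sum(pi)
    Tt <- sum(ti)
    den <- P + Tt + eps
    loss <- loss + 1 - (2 * I + eps) / den
    grad[, , , i] <- -(2 * ti * den - (2 * I + eps)) / den^2 / n
  }
  list(loss = loss / n, grad = grad)
}

check_binary <- function(m, what = "mask") {
  if (!all(m %in% c(0, 1))) stop(what, " must be strictly binary {0,1}")
  invisible(TRUE)
}

#' Pixel confusion counts between two binary masks
#'
#' @param pred,target binary matrices of identical shape; 1 = foreground.
#' @return List with `tp`, `fp`, `fn`, `tn` pixel counts (foreground taken
#'   as the positive class).
#' @export
confusion_counts <- function(pred, target) {
  if (!identical(dim(pred), dim(target))) stop("mask shapes differ")
  check_binary(pred, "pred")
  check_binary(target, "target")
  tp <- sum(pred == 1 & target == 1)
  fp <- sum(pred == 1 & target == 0)
  fn <- sum(pred == 0 & target == 1)
  list(tp = tp, fp = fp, fn = fn, tn = length(pred) - tp - fp - fn)
}

#' Overlap indices from confusion counts
#'
#' Computes the four standard area-overlap indices:
#' `DSC = 2TP / (2TP + FP + FN)`, `JSC = TP / (TP + FP + FN)`,
#' `PPV = TP / (TP + FP)`, `SE = TP / (TP + FN)`.  When both masks are
#' empty, DSC and JSC are reported as 1 (perfect agreement on emptiness);
#' PPV and SE are `NA` when their denominator is zero (undefined, to be
#' excluded from aggregation).
#'
#' @param counts list from [confusion_counts()] (or any list with
#'   `tp`, `fp`, `fn`).
#' @return Named numeric vector `dsc`, `jsc`, `ppv`, `se`, each in `[0, 1]`
#'   (or `NA` where undefined).
#' @export
overlap_metrics <- function(counts) {
  tp <- counts$tp; fp <- counts$fp; fn <- counts$fn
  dsc <- if (2 * tp + fp + fn == 0) 1 else 2 * tp / (2 * tp + fp + fn)
  jsc <- if (tp + fp + fn == 0) 1 else tp / (tp + fp + fn)
  ppv <- if (tp + fp == 0) NA_real_ else tp / (tp + fp)
  se <- if (tp + fn == 0) NA_real_ else tp / (tp + fn)
  c(dsc = dsc, jsc = jsc, ppv = ppv, se = se)
}

#' Exact symmetric Hausdorff distance between mask foregrounds
#'
#' `H(X, Y) = max(h(X, Y), h(Y, X))` with
#' `h(X, Y) = max_{x in X} min_{y in Y} ||x - y||`, the directed max-min
#' Euclidean distance between the two foreground point sets (pixel centers
#' scaled by `spacing`).  The exact maximum is used, not a percentile
#' approximation.
#'
#' @param pred,target binary matrices of identical shape, both nonempty.
#' @param spacing length-2 numeric, physical size of a pixel along (row,
#'   col); default `c(1, 1)` reports the distance in pixels.
#' @return Scalar distance `>= 0`; `Inf` if exactly one mask is empty, and
#'   0 if both are empty (nothing to disagree about).
#' @export
hausdorff_distance <- function(pred, target, spacing = c(1, 1)) {
  if (!identical(dim(pred), dim(target))) stop("mask shapes differ")
  check_binary(pred, "pred")
  check_binary(target, "target")
  a <- which(pred == 1, arr.ind = TRUE)
  b <- which(target == 1, arr.ind = TRUE)
  if (nrow(a) == 0 && nrow(b) == 0) return(0)
  if (nrow(a) == 0 || nrow(b) == 0) return(Inf)
  a <- sweep(a, 2, spacing, `*`)
  b <- sweep(b, 2, spacing, `*`)
  max(directed_hausdorff(a, b), directed_hausdorff(b, a))
}

# max over rows of `a` of the min distance to rows of `b`, chunked so the
# cross-distance matrix stays small.
directed_hausdorff <- function(a, b, chunk = 2048L) {
  worst <- 0
  bt1 <- b[, 1]; bt2 <- b[, 2]
  for (s in seq(1L, nrow(a), by = chunk)) {
    idx <- s:min(s + chunk - 1L, nrow(a))
    d2 <- outer(a[idx, 1], bt1, `-`)^2 + outer(a[idx, 2], bt2, `-`)^2
    worst <- max(worst, max(apply(d2, 1, min)))
  }
  sqrt(worst)
}

#' Per-case metric vector for one mask pair
#'
#' Convenience wrapper computing DSC/JSC/PPV/SE via [overlap_metrics()] and
#' HD via [hausdorff_distance()] for a single predicted/reference pair.
#'
#' @inheritParams hausdorff_distance
#' @return Named numeric vector `dsc, jsc, ppv, se, hd`.
#' @export
metric_vector <- function(pred, target, spacing = c(1, 1)) {
  c(overlap_metrics(confusion_counts(pred, target)),
    hd = hausdorff_distance(pred, target, spacing))
}
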