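# Independent brute-force oracles and small fixture builders, kept free of
# the package's own metric code paths.

# Explicit pixel-by-pixel confusion counting (double loop).
oracle_confusion <- function(pred, target) {
  tp <- fp <- fn <- tn <- 0L
  for (i in seq_len(nrow(pred))) {
    for (j in seq_len(ncol(pred))) {
      p <- pred[i, j]
      t <- target[i, j]
      if (p == 1 && t == 1) tp <- tp + 1L
      else if (p == 1 && t == 0) fp <- fp + 1L
      else if (p == 0 && t == 1) fn <- fn + 1L
      else tn <- tn + 1L
    }
  }
  list(tp = tp, fp = fp, fn = fn, tn = tn)
}

oracle_overlap <- function(pred, target) {
  cc <- oracle_confusion(pred, target)
  with(cc, c(dsc = if (2 * tp + fp + fn == 0) 1 else 2 * tp / (2 * tp + fp + fn),
             jsc = if (tp + fp + fn == 0) 1 else tp / (tp + fp + fn),
             ppv = if (tp + fp == 0) NA_real_ else tp / (tp + fp),
             se = if (tp + fn == 0) NA_real_ else tp / (tp + fn)))
}

# All-pairs directed max-min distance, explicit loops.
oracle_hausdorff <- function(pred, target, spacing = c(1, 1)) {
  a <- which(pred == 1, arr.ind = TRUE)
  b <- which(target == 1, arr.ind = TRUE)
  dir_h <- function(p, q) {
    worst <- 0
    for (i in seq_len(nrow(p))) {
      best <- Inf
      for (j in seq_len(nrow(q))) {
        d <- sqrt(((p[i, 1] - q[j, 1]) * spacing[1])^2 +
                  ((p[i, 2] - q[j, 2]) * spacing[2])^2)
        if (d < best) best <- d
      }
      if (best > worst) worst <- best
    }
    worst
  }
  max(dir_h(a, b), dir_h(b, a))
}

# Random blob-ish binary mask (union of a few rectangles), possibly empty
# unless min_fg > 0.
random_mask <- function(h, w, blobs = 3, min_fg = 1) {
  m <- matrix(0, h, w)
  for (k in seq_len(blobs)) {
    r0 <- sample(h, 1); c0 <- sample(w, 1)
    r1 <- min(h, r0 + sample(0:(h %/% 3), 1))
    c1 <- min(w, c0 + sample(0:(w %/% 3), 1))
    m[r0:r1, c0:c1] <- 1
  }
  while (sum(m) < min_fg) m[sample(h, 1), sample(w, 1)] <- 1
  m
}

# Small noise-free phantom batch used by optimization tests.  `hu` holds
# raw slices for the training interface (which windows internally);
# `images` holds already-windowed [0,1] inputs for direct engine calls.
noise_free_phantoms <- function(n = 4, size = 64, seed = 2) {
  cfg <- phantom_config(image_size = size, noise_sd = 0, vessel_count = 0,
                        seed = seed)
  phs <- lapply(seq_len(n), function(i) generate_phantom(cfg, i))
  list(hu = lapply(phs, function(p) p$image),
       images = lapply(phs, function(p) apply_window(p$image)),
       masks = lapply(phs, function(p) p$mask))
}

# Finite-difference gradient of a scalar-valued function of one array slot.
fd_grad <- function(f, x, i, h = 1e-6) {
  xp <- x; xp[i] <- xp[i] + h
  xm <- x; xm[i] <- xm[i] - h
  (f(xp) - f(xm)) / (2 * h)
}
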