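# CT preprocessing: stored pixels -> HU -> window/level -> CLAHE, and
# label-consistent geometric augmentation.  Contrast enhancement and
# warping are delegated to EBImage; this file owns the conventions
# (window mapping, mask re-binarization, transform composition).

#' Convert stored CT pixels to Hounsfield units
#'
#' Elementwise affine rescale `hu = raw * slope + intercept` using the
#' slope/intercept metadata carried by CT DICOM headers.
#'
#' @param raw stored-pixel matrix or array.
#' @param slope,intercept rescale parameters (typically 1 and -1024).
#' @return HU-valued numeric array of the same shape.
#' @export
pixels_to_hu <- function(raw, slope = 1, intercept = -1024) {
  if (!is.finite(slope) || !is.finite(intercept))
    stop("slope and intercept must be finite")
  raw * slope + intercept
}

#' Window specification
#'
#' @param level window center in HU; @param width window width in HU (> 0).
#'   The default 60/400 soft-tissue neck window brackets thyroid tissue
#'   (roughly 60-100 HU).
#' @export
window_spec <- function(level = 60, width = 400) {
  if (width <= 0) stop("window width must be > 0")
  structure(list(level = level, width = width), class = "window_spec")
}

#' Apply a window/level mapping
#'
#' Clips HU values to `[level - width/2, level + width/2]` and maps the
#' interval linearly to `[0, 1]`; monotone nondecreasing in the input.
#'
#' @param hu HU-valued matrix or array.
#' @param window a [window_spec()].
#' @return Image in `[0, 1]`, same shape.
#' @export
apply_window <- function(hu, window = window_spec()) {
  lo <- window$level - window$width / 2
  x <- (hu - lo) / window$width
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}

#' Contrast-limited adaptive histogram equalization
#'
#' Tile-based contrast enhancement with clip limiting and bilinear blending
#' across tile borders (CLAHE), used to enhance soft-tissue contrast after
#' windowing.  A constant image stays (near-)constant: there is no contrast
#' to enhance.
#'
#' @param img image in `[0, 1]`.
#' @param tiles tile grid, `c(nx, ny)` (default 8x8).
#' @param clip_limit contrast-limit factor (multiple of the mean histogram
#'   count; higher = stronger enhancement).
#' @param bins histogram resolution per tile.
#' @return Equalized image in `[0, 1]`.
#' @export
adaptive_hist_equalize <- function(img, tiles = c(8L, 8L), clip_limit = 2,
                                   bins = 256L) {
  d <- dim(img)
  if (any(tiles > d))
    stop("tile grid (", paste(tiles, collapse = "x"),
         ") larger than image (", paste(d, collapse = "x"), ")")
  if (diff(range(img)) == 0) return(img)   # nothing to equalize
  out <- EBImage::clahe(img, nx = tiles[1], ny = tiles[2], bins = bins,
                        limit = clip_limit)
  out <- as.numeric(out)
  dim(out) <- d
  out[out < 0] <- 0
  out[out > 1] <- 1
  out
}

#' Augmentation specification
#'
#' One concrete geometric transform from the standard augmentation family
#' for this task: rotation, flipping, zooming, shearing.  The identity
#' transform is the default.
#'
#' @param rotation_deg rotation angle in degrees (counterclockwise about
#'   the image center).
#' @param flip_horizontal logical, mirror about the vertical center line.
#' @param zoom_factor isotropic scale about the center (> 0; > 1 zooms in).
#' @param shear_deg horizontal shear angle in degrees.
#' @export
augment_spec <- function(rotation_deg = 0, flip_horizontal = FALSE,
                         zoom_factor = 1, shear_deg = 0) {
  if (zoom_factor <= 0) stop("zoom_factor must be > 0")
  structure(list(rotation_deg = rotation_deg,
                 flip_horizontal = flip_horizontal,
                 zoom_factor = zoom_factor, shear_deg = shear_deg),
            class = "augment_spec")
}

#' Sample a random augmentation spec
#'
#' Draws one transform from the configured ranges: rotation +-15 degrees,
#' zoom 0.9-1.1, shear +-8 degrees, horizontal flip with probability 0.5
#' by default (applied on the fly during training).
#'
#' @param rotation_range,zoom_range,shear_range numeric length-2 ranges.
#' @param flip_prob probability of a horizontal flip.
#' @return An [augment_spec()] drawn from the current RNG stream.
#' @export
sample_augment_spec <- function(rotation_range = c(-15, 15),
                                zoom_range = c(0.9, 1.1),
                                shear_range = c(-8, 8), flip_prob = 0.5) {
  augment_spec(rotation_deg = stats::runif(1, rotation_range[1], rotation_range[2]),
               flip_horizontal = stats::runif(1) < flip_prob,
               zoom_factor = stats::runif(1, zoom_range[1], zoom_range[2]),
               shear_deg = stats::runif(1, shear_range[1], shear_range[2]))
}

# Forward affine map (2x3, homogeneous) for a spec, about the image center,
# in EBImage point coordinates.
augment_matrix <- function(spec, d) {
  th <- spec$rotation_deg * pi / 180
  sh <- tan(spec$shear_deg * pi / 180)
  z <- spec$zoom_factor
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  Sh <- matrix(c(1, 0, sh, 1), 2, 2)
  F <- if (spec$flip_horizontal) diag(c(-1, 1)) else diag(2)
  A <- F %*% R %*% Sh %*% diag(c(z, z))
  ctr <- d / 2
  off <- ctr - A %*% ctr
  cbind(A, off)   # 2 x 3
}

#' Apply one augmentation to an image/mask pair
#'
#' The identical geometric transform is applied to both: the image is
#' interpolated bilinearly, the mask with nearest neighbor and re-binarized
#' at 0.5.  Output keeps the input size (regions mapped from outside are
#' filled with 0).
#'
#' @param img image matrix (any real values).
#' @param mask binary mask matrix, same shape.
#' @param spec an [augment_spec()].
#' @return List `img`, `mask` (mask strictly in {0,1}).
#' @export
augment_pair <- function(img, mask, spec = augment_spec()) {
  if (!identical(dim(img), dim(mask))) stop("img and mask shapes differ")
  if (identical(unclass(spec), unclass(augment_spec())))
    return(list(img = img, mask = mask))
  m <- augment_matrix(spec, dim(img))
  em <- t(rbind(m, c(0, 0, 1)))[, 1:2]   # EBImage expects 3x2, y = cbind(x,1) %*% m
  wi <- EBImage::affine(img, em, filter = "bilinear", output.dim = dim(img),
                        bg.col = 0, antialias = FALSE)
  wm <- EBImage::affine(mask, em, filter = "none", output.dim = dim(mask),
                        bg.col = 0, antialias = FALSE)
  wi <- matrix(as.numeric(wi), nrow(img), ncol(img))
  wm <- matrix(as.numeric(wm), nrow(mask), ncol(mask))
  list(img = wi, mask = (wm >= 0.5) * 1)
}
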