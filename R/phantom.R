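# Deterministic CT-like phantom generator.
#
# Each phantom is a 2-D HU-valued slice containing a bilobed soft-tissue
# gland (two ellipses joined by an isthmus band, thyroid-like HU range)
# surrounded by vessel-like circular confounders whose HU range overlaps
# the gland's -- so telling gland from vessel is an intensity problem, not
# a label-noise problem -- plus uniform neck soft tissue and additive
# Gaussian noise.  Generation is a pure function of (config, index): the
# per-phantom RNG stream is seeded with config$seed + index.

#' Phantom generator configuration
#'
#' @param image_size pixels per side (>= 32); 512 matches clinical CT
#'   localization slices, 64 keeps desk-scale experiments fast.
#' @param gland_hu_range HU interval of gland tissue (default 60-100,
#'   standard thyroid soft-tissue range).
#' @param background_hu HU of surrounding neck soft tissue (default 40).
#' @param vessel_count number of vessel-like circular confounders (>= 0).
#' @param vessel_hu_range HU interval of vessels; overlaps the gland range
#'   by default so confounders have similar gray levels.
#' @param noise_sd standard deviation of additive Gaussian noise, in HU.
#' @param lobe_size_range lobe width as a fraction of image width
#'   (min, max); lobes are jittered per phantom within this range.
#' @param seed global integer seed; phantom `index` uses stream
#'   `seed + index`.
#' @return A validated `phantom_config` list.
#' @export
phantom_config <- function(image_size = 512L, gland_hu_range = c(60, 100),
                           background_hu = 40, vessel_count = 12L,
                           vessel_hu_range = c(60, 100), noise_sd = 8,
                           lobe_size_range = c(0.10, 0.16), seed = 1L) {
  cfg <- list(image_size = as.integer(image_size),
              gland_hu_range = as.numeric(gland_hu_range),
              background_hu = as.numeric(background_hu),
              vessel_count = as.integer(vessel_count),
              vessel_hu_range = as.numeric(vessel_hu_range),
              noise_sd = as.numeric(noise_sd),
              lobe_size_range = as.numeric(lobe_size_range),
              seed = as.integer(seed))
  if (cfg$image_size < 32L)
    stop("image_size must be >= 32 to place two lobes")
  if (cfg$gland_hu_range[1] > cfg$gland_hu_range[2])
    stop("gland_hu_range must satisfy low <= high")
  if (cfg$vessel_hu_range[1] > cfg$vessel_hu_range[2])
    stop("vessel_hu_range must satisfy low <= high")
  if (cfg$vessel_count < 0L) stop("vessel_count must be >= 0")
  if (cfg$noise_sd < 0) stop("noise_sd must be >= 0")
  if (any(cfg$lobe_size_range <= 0) || cfg$lobe_size_range[1] > cfg$lobe_size_range[2])
    stop("lobe_size_range must be a positive interval")
  class(cfg) <- "phantom_config"
  cfg
}

#' Generate one phantom slice with its ground-truth mask
#'
#' Draws the bilobed gland (two axis-aligned ellipses plus a connecting
#' isthmus band) at gland HU, rejection-samples `vessel_count` circular
#' confounders so they never overlap the gland mask, then adds Gaussian
#' noise.  The mask marks exactly the gland pixels before noise.  Calling
#' with the same `(config, index)` regenerates bit-identical output.
#'
#' @param config a [phantom_config()].
#' @param index nonnegative integer identifying the phantom within the
#'   configured stream.
#' @return List of class `phantom_pair`: `image` (HU matrix), `mask`
#'   (binary matrix), `config`, `index`.
#' @export
generate_phantom <- function(config = phantom_config(), index = 1L) {
  if (!inherits(config, "phantom_config")) config <- do.call(phantom_config, config)
  old <- .save_rng()
  on.exit(.restore_rng(old), add = TRUE)
  set.seed((config$seed + as.integer(index)) %% .Machine$integer.max)

  S <- config$image_size
  xc <- matrix(rep(seq_len(S), each = S), S, S)   # column index
  yc <- matrix(rep(seq_len(S), times = S), S, S)  # row index

  # gland geometry, jittered per index
  f <- stats::runif(1, config$lobe_size_range[1], config$lobe_size_range[2])
  a <- max(2, f * S / 2)                      # lobe horizontal semi-axis
  b <- a * stats::runif(1, 1.4, 1.8)          # lobes are taller than wide
  cx <- S * stats::runif(1, 0.45, 0.55)
  cy <- S * stats::runif(1, 0.40, 0.55)
  gap <- a * stats::runif(1, 0.5, 0.9)        # half-distance between lobes
  dx <- a + gap
  b1 <- b * stats::runif(1, 0.9, 1.1)
  b2 <- b * stats::runif(1, 0.9, 1.1)

  in_ell <- function(cx0, cy0, a0, b0)
    ((xc - cx0) / a0)^2 + ((yc - cy0) / b0)^2 <= 1
  mask <- in_ell(cx - dx, cy, a, b1) | in_ell(cx + dx, cy, a, b2)
  ih <- max(1, 0.35 * b)                      # isthmus half-height
  mask <- mask | (abs(yc - cy) <= ih & abs(xc - cx) <= dx)
  mask <- mask * 1

  img <- matrix(config$background_hu, S, S)
  ng <- sum(mask)
  img[mask == 1] <- stats::runif(ng, config$gland_hu_range[1],
                                 config$gland_hu_range[2])

  # vessel confounders, rejection-sampled to stay off the gland
  placed <- 0L
  tries <- 0L
  while (placed < config$vessel_count && tries < 200L * max(1L, config$vessel_count)) {
    tries <- tries + 1L
    r <- max(1, stats::runif(1, 0.01, 0.03) * S)
    vx <- stats::runif(1, r + 1, S - r)
    vy <- stats::runif(1, r + 1, S - r)
    circ <- (xc - vx)^2 + (yc - vy)^2 <= r^2
    if (any(circ & mask == 1)) next
    hu <- stats::runif(1, config$vessel_hu_range[1], config$vessel_hu_range[2])
    img[circ] <- hu
    placed <- placed + 1L
  }

  if (config$noise_sd > 0)
    img <- img + matrix(stats::rnorm(S * S, 0, config$noise_sd), S, S)

  structure(list(image = img, mask = mask, config = config,
                 index = as.integer(index)),
            class = "phantom_pair")
}

#' Write a phantom dataset to disk
#'
#' Writes `n` image/mask pairs -- images as single-frame DICOM (stored
#' pixels `HU + 1024`, RescaleSlope 1, RescaleIntercept -1024), masks as
#' 8-bit PNG (0/255) -- plus `manifest.csv` (case_id, image_path,
#' mask_path) and `phantom_config.json`.  Re-running with the same config
#' reproduces byte-identical files (DICOM UIDs are derived from the seed
#' and index, never from the clock).
#'
#' @param config a [phantom_config()].
#' @param n number of phantoms (>= 1).
#' @param out_dir output directory (created if missing).
#' @return The manifest as a data frame, invisibly;
#'   also written to `<out_dir>/manifest.csv`.
#' @export
generate_dataset <- function(config = phantom_config(), n, out_dir) {
  if (n < 1) stop("n must be >= 1")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    ph <- generate_phantom(config, i)
    case <- sprintf("case_%03d", i)
    ipath <- file.path(out_dir, paste0(case, ".dcm"))
    mpath <- file.path(out_dir, paste0(case, "_mask.png"))
    write_dicom_slice(ph$image, ipath, case_id = case,
                      uid_suffix = paste0(config$seed, ".", i))
    write_mask_png(ph$mask, mpath)
    rows[[i]] <- data.frame(case_id = case, image_path = ipath,
                            mask_path = mpath, stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  jsonlite::write_json(unclass(config),
                       file.path(out_dir, "phantom_config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
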