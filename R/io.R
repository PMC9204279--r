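# Mask PNG I/O and the patient-level dataset split.

#' Read / write binary segmentation masks as PNG
#'
#' On disk masks are 8-bit grayscale with polarity 0/255; in memory they
#' are 0/1 matrices (row-major, origin top-left).  Any nonzero pixel reads
#' as foreground, so `read_mask_png(write_mask_png(m)) == m`.  RGB files
#' are converted via luminance with a warning.
#'
#' @param path PNG file path.
#' @return `read_mask_png`: binary 0/1 matrix.
#' @export
read_mask_png <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 3L) {
    warning("RGB(A) mask ", path, "; converting via luminance")
    a <- 0.299 * a[, , 1] + 0.587 * a[, , 2] + 0.114 * a[, , 3]
  }
  (a > 0) * 1
}

#' @rdname read_mask_png
#' @param mask binary 0/1 matrix.
#' @export
write_mask_png <- function(mask, path) {
  check_binary(mask)
  png::writePNG(mask, path)
  invisible(path)
}

#' Split cases into training / validation / test sets
#'
#' Shuffles case ids with the given seed and partitions them by the ratio
#' using largest-remainder rounding, so 80 cases at the study's 6:1:1
#' ratio give exactly 60/10/10.  The split is by case (patient), never by
#' slice, so all slices of one patient land in the same partition.
#'
#' @param case_ids character or integer vector of distinct case ids.
#' @param ratios length-3 positive weights for train/validation/test
#'   (default `c(6, 1, 1)`).
#' @param seed integer seed for the shuffle.
#' @return List of class `dataset_split` with `train`, `validation`,
#'   `test`; the three are disjoint and their union is `case_ids`.
#' @export
split_dataset <- function(case_ids, ratios = c(6, 1, 1), seed = 1L) {
  n <- length(case_ids)
  if (n < length(ratios)) stop("need at least ", length(ratios), " cases")
  if (any(ratios <= 0) || length(ratios) != 3L)
    stop("ratios must be 3 positive weights")
  old <- .save_rng()
  on.exit(.restore_rng(old), add = TRUE)
  set.seed(seed)
  ids <- sample(case_ids)
  exact <- n * ratios / sum(ratios)
  sizes <- floor(exact)
  rem <- n - sum(sizes)
  if (rem > 0) {
    extra <- order(exact - sizes, decreasing = TRUE)[seq_len(rem)]
    sizes[extra] <- sizes[extra] + 1
  }
  while (any(sizes == 0)) {           # every partition gets at least 1 case
    sizes[which.max(sizes)] <- max(sizes) - 1
    sizes[which(sizes == 0)[1]] <- 1
  }
  cuts <- cumsum(sizes)
  structure(list(train = ids[seq_len(cuts[1])],
                 validation = ids[(cuts[1] + 1):cuts[2]],
                 test = ids[(cuts[2] + 1):cuts[3]]),
            class = "dataset_split")
}

#' @export
print.dataset_split <- function(x, ...) {
  cat(sprintf("dataset split: %d train / %d validation / %d test\n",
              length(x$train), length(x$validation), length(x$test)))
  invisible(x)
}

# Attach a split to a manifest data frame as a `split` column.
apply_split <- function(manifest, split) {
  manifest$split <- NA_character_
  manifest$split[manifest$case_id %in% split$train] <- "train"
  manifest$split[manifest$case_id %in% split$validation] <- "validation"
  manifest$split[manifest$case_id %in% split$test] <- "test"
  manifest
}
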