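# Test-set evaluation: per-case metric vectors, mean +- sd aggregation and
# box-plot summaries, in the reporting style of a segmentation study table.

#' Evaluate predicted masks against references
#'
#' Computes DSC, JSC, PPV, SE and Hausdorff distance per case, then
#' aggregates each index as mean +- standard deviation across cases and
#' derives box-plot statistics (median, quartiles, whiskers, outliers).
#' Undefined per-case values (PPV/SE with empty denominators) are excluded
#' from aggregation.
#'
#' @param pred list of binary matrices, or a directory / vector of PNG
#'   paths.
#' @param target same-length references, same formats accepted.
#' @param spacing per-axis pixel size for the Hausdorff distance (default
#'   pixels).
#' @param case_ids optional case labels; defaults to file names or an
#'   index.
#' @return Object of class `metric_report`: `per_case` data frame
#'   (case_id, dsc, jsc, ppv, se, hd), `summary` data frame (metric, mean,
#'   sd, n), `boxstats` list of `grDevices::boxplot.stats` per metric.
#' @export
evaluate_masks <- function(pred, target, spacing = c(1, 1), case_ids = NULL) {
  pred <- as_mask_list(pred)
  target <- as_mask_list(target)
  if (length(pred) != length(target))
    stop("prediction and reference counts differ (",
         length(pred), " vs ", length(target), ")")
  if (is.null(case_ids))
    case_ids <- names(pred) %||% sprintf("case_%03d", seq_along(pred))
  per <- do.call(rbind, lapply(seq_along(pred), function(i) {
    v <- metric_vector(pred[[i]], target[[i]], spacing)
    data.frame(case_id = case_ids[i], dsc = v["dsc"], jsc = v["jsc"],
               ppv = v["ppv"], se = v["se"], hd = v["hd"],
               row.names = NULL)
  }))
  metrics <- c("dsc", "jsc", "ppv", "se", "hd")
  summ <- do.call(rbind, lapply(metrics, function(m) {
    x <- per[[m]][is.finite(per[[m]])]
    data.frame(metric = m, mean = mean(x),
               sd = if (length(x) > 1) stats::sd(x) else 0,
               n = length(x))
  }))
  box <- lapply(metrics, function(m)
    grDevices::boxplot.stats(per[[m]][is.finite(per[[m]])]))
  names(box) <- metrics
  structure(list(per_case = per, summary = summ, boxstats = box),
            class = "metric_report")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

as_mask_list <- function(x) {
  if (is.matrix(x)) return(list(x))
  if (is.character(x)) {
    if (length(x) == 1L && dir.exists(x))
      x <- sort(list.files(x, pattern = "\\.png$", full.names = TRUE))
    masks <- lapply(x, read_mask_png)
    names(masks) <- sub("\\.png$", "", basename(x))
    return(masks)
  }
  if (is.list(x)) return(x)
  stop("unrecognized mask input")
}

#' @export
print.metric_report <- function(x, digits = 3, ...) {
  cat(sprintf("Segmentation metrics over %d case(s) (mean ± sd):\n",
              nrow(x$per_case)))
  if (nrow(x$per_case) == 1L) cat("  (n = 1: sd is 0 by convention)\n")
  for (i in seq_len(nrow(x$summary))) {
    r <- x$summary[i, ]
    cat(sprintf("  %-4s %s ± %s\n", toupper(r$metric),
                format(round(r$mean, digits), nsmall = digits),
                format(round(r$sd, digits), nsmall = digits)))
  }
  invisible(x)
}

#' Write a metric report to CSV
#'
#' Writes the per-case table (`<path>`) and the mean/sd summary
#' (`<path stem>_summary.csv`).
#' @param report a `metric_report`; @param path output CSV path.
#' @export
write_metric_report <- function(report, path) {
  utils::write.csv(report$per_case, path, row.names = FALSE)
  utils::write.csv(report$summary,
                   sub("(\\.csv)?$", "_summary.csv", path, perl = TRUE)[1],
                   row.names = FALSE)
  invisible(path)
}

#' Box-plot of per-case metrics
#' @param x a `metric_report`; @param ... passed to `boxplot`.
#' @export
plot.metric_report <- function(x, ...) {
  graphics::boxplot(x$per_case[, c("dsc", "jsc", "ppv", "se")],
                    ylab = "index value", ...)
  invisible(x)
}
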