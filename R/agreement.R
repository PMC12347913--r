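# pixel-level agreement between two segmentations

#' Pixel agreement between a test and a reference segmentation for one class
#'
#' Computes true/false positive and false negative areas by pixel
#' intersection within an evaluation region, and reports precision
#' (`100 * TP / (TP + FP)`), sensitivity (`100 * TP / (TP + FN)`), their
#' harmonic-mean F1, and the false positive/negative areas as a percentage of
#' the evaluation region.
#'
#' @param test,reference [labeled_section()]s on the same raster frame and
#'   calibration.
#' @param class class name or code.
#' @param region evaluation-region rule for the FP%/FN% denominator:
#'   `"tissue"` (union of both sections' Tissue masks, default), `"frame"`
#'   (whole raster), or `"class_union"` (union of the class in both sections).
#' @return One-row data.frame: `class_name`, `comparison`, `fp_pct`, `fn_pct`,
#'   `precision`, `sensitivity`, `f1`, `eval_area_um2`, `defined`. When the
#'   class is absent from both sections all metrics are `NA` with
#'   `defined = FALSE`.
#' @export
pairwise_agreement <- function(test, reference, class,
                               region = c("tissue", "frame", "class_union")) {
  region <- match.arg(region)
  if (!identical(test$dim, reference$dim))
    stop("sections are on different raster frames")
  if (!identical(test$calibration$microns_per_pixel,
                 reference$calibration$microns_per_pixel))
    stop("sections have different calibrations")
  mpp <- test$calibration$microns_per_pixel
  name <- taxonomy_class(test$taxonomy, class)$name
  mt <- class_mask(test, name)
  mr <- class_mask(reference, name)
  reg <- switch(region,
    tissue = class_mask(test, .cls$tissue) |
      class_mask(reference, .cls$tissue),
    frame = matrix(TRUE, test$dim[1], test$dim[2]),
    class_union = mt | mr)
  mt <- mt & reg; mr <- mr & reg
  tp <- sum(mt & mr); fp <- sum(mt & !mr); fn <- sum(!mt & mr)
  reg_area <- sum(reg)
  row <- data.frame(class_name = name, comparison = "pairwise",
                    fp_pct = NA_real_, fn_pct = NA_real_,
                    precision = NA_real_, sensitivity = NA_real_,
                    f1 = NA_real_, eval_area_um2 = reg_area * mpp^2,
                    defined = FALSE)
  if (tp + fp + fn == 0) return(row)   # class absent in both
  p <- if (tp + fp > 0) 100 * tp / (tp + fp) else NA_real_
  s <- if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_
  f1 <- if (!is.na(p) && !is.na(s) && p + s > 0) 2 * p * s / (p + s)
        else NA_real_
  row$fp_pct <- if (reg_area > 0) 100 * fp / reg_area else NA_real_
  row$fn_pct <- if (reg_area > 0) 100 * fn / reg_area else NA_real_
  row$precision <- p; row$sensitivity <- s; row$f1 <- f1
  row$defined <- TRUE
  row
}

#' Model-vs-panel and within-panel agreement for one class
#'
#' Aggregates pairwise pixel agreement over an annotator panel: the
#' model-vs-panel row averages the model against each annotator as reference;
#' the within-panel row averages all ordered annotator pairs (both directions,
#' so the precision/sensitivity swap symmetry is explicit in the average).
#'
#' @param model a [labeled_section()] (the automated segmentation).
#' @param annotators list of at least two [labeled_section()]s.
#' @param class class name or code.
#' @param region evaluation region, see [pairwise_agreement()].
#' @param aggregate `"mean"` (default) averages per-pair metrics;
#'   `"pooled"` sums TP/FP/FN areas over pairs before computing metrics.
#' @return Two-row data.frame (comparisons `"model_vs_panel"` and
#'   `"within_panel"`) with the columns of [pairwise_agreement()].
#' @export
panel_agreement <- function(model, annotators, class,
                            region = c("tissue", "frame", "class_union"),
                            aggregate = c("mean", "pooled")) {
  region <- match.arg(region)
  aggregate <- match.arg(aggregate)
  if (length(annotators) < 2)
    stop("within-panel agreement needs at least 2 annotators")
  rows_model <- lapply(annotators, function(a)
    pairwise_agreement(model, a, class, region))
  pairs <- expand.grid(i = seq_along(annotators), j = seq_along(annotators))
  pairs <- pairs[pairs$i != pairs$j, ]
  rows_panel <- mapply(function(i, j)
    pairwise_agreement(annotators[[i]], annotators[[j]], class, region),
    pairs$i, pairs$j, SIMPLIFY = FALSE)
  agg <- function(rows, label) {
    df <- do.call(rbind, rows)
    out <- df[1, , drop = FALSE]
    out$comparison <- label
    metric_cols <- c("fp_pct", "fn_pct", "precision", "sensitivity", "f1",
                     "eval_area_um2")
    if (any(df$defined)) {
      for (cn in metric_cols) out[[cn]] <- mean(df[[cn]][df$defined])
    } else {
      for (cn in metric_cols) out[[cn]] <- NA_real_
    }
    out$defined <- any(df$defined)
    out
  }
  if (aggregate == "pooled") {
    pool <- function(a_list, label) {
      tp <- fp <- fn <- reg_area <- 0
      mpp <- model$calibration$microns_per_pixel
      name <- taxonomy_class(model$taxonomy, class)$name
      for (ab in a_list) {
        ta <- ab[[1]]; rb <- ab[[2]]
        mt <- class_mask(ta, name); mr <- class_mask(rb, name)
        reg <- switch(region,
          tissue = class_mask(ta, .cls$tissue) | class_mask(rb, .cls$tissue),
          frame = matrix(TRUE, ta$dim[1], ta$dim[2]),
          class_union = mt | mr)
        mt <- mt & reg; mr <- mr & reg
        tp <- tp + sum(mt & mr); fp <- fp + sum(mt & !mr)
        fn <- fn + sum(!mt & mr); reg_area <- reg_area + sum(reg)
      }
      p <- if (tp + fp > 0) 100 * tp / (tp + fp) else NA_real_
      s <- if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_
      data.frame(class_name = name, comparison = label,
                 fp_pct = 100 * fp / reg_area, fn_pct = 100 * fn / reg_area,
                 precision = p, sensitivity = s,
                 f1 = if (!is.na(p) && !is.na(s) && p + s > 0)
                   2 * p * s / (p + s) else NA_real_,
                 eval_area_um2 = reg_area * mpp^2 / length(a_list),
                 defined = tp + fp + fn > 0)
    }
    model_row <- pool(lapply(annotators, function(a) list(model, a)),
                      "model_vs_panel")
    panel_row <- pool(mapply(function(i, j)
      list(annotators[[i]], annotators[[j]]), pairs$i, pairs$j,
      SIMPLIFY = FALSE), "within_panel")
    return(rbind(model_row, panel_row))
  }
  rbind(agg(rows_model, "model_vs_panel"), agg(rows_panel, "within_panel"))
}
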