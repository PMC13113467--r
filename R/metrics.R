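#' One-vs-rest confusion counts per class
#'
#' For every class of the schema (background included), counts the pixels
#' that are true/false positives/negatives of the one-vs-rest problem. For
#' every class `TP + FP + TN + FN` equals the number of pixels.
#'
#' @param pred,truth Equal-shaped integer label masks.
#' @param schema A [label_schema()].
#' @return A `confusion_counts` object (per-class tp/fp/fn/tn vectors).
#' @export
confusion_counts <- function(pred, truth, schema) {
  assert_that(all(dim(pred) == dim(truth)), "pred/truth shape mismatch")
  ids <- unname(schema$classes)
  assert_that(all(pred %in% ids) && all(truth %in% ids),
              "mask values outside schema ids")
  tab <- table(factor(as.integer(pred), levels = ids),
               factor(as.integer(truth), levels = ids))
  tp <- unname(as.numeric(diag(tab)))
  fp <- unname(rowSums(tab)) - tp
  fn <- unname(colSums(tab)) - tp
  n <- length(pred)
  structure(list(ids = ids, names = names(schema$classes),
                 tp = tp, fp = fp, fn = fn, tn = n - tp - fp - fn,
                 n_pixels = n),
            class = "confusion_counts")
}

#' Pool confusion counts over images
#' @param ... `confusion_counts` objects over the same schema.
#' @return Pooled `confusion_counts`.
#' @export
pool_confusion <- function(...) {
  cs <- list(...)
  if (length(cs) == 1 && is.list(cs[[1]]) &&
      !inherits(cs[[1]], "confusion_counts")) {
    cs <- cs[[1]]
  }
  out <- cs[[1]]
  for (cc in cs[-1]) {
    assert_that(identical(cc$ids, out$ids), "schema mismatch when pooling")
    out$tp <- out$tp + cc$tp; out$fp <- out$fp + cc$fp
    out$fn <- out$fn + cc$fn; out$tn <- out$tn + cc$tn
    out$n_pixels <- out$n_pixels + cc$n_pixels
  }
  out
}

#' Per-class pixel accuracy, Dice and IoU from confusion counts
#'
#' `PA = (TP + TN) / N`, `Dice = 2TP / (2TP + FP + FN)`,
#' `IoU = TP / (TP + FP + FN)`. A class with `TP + FP + FN = 0` (absent from
#' both masks) is flagged unevaluable rather than producing 0/0.
#'
#' @param counts A [confusion_counts()].
#' @return Data frame with columns `class`, `id`, `PA`, `Dice`, `IoU`,
#'   `evaluable`.
#' @export
per_class_metrics <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  denom <- counts$tp + counts$fp + counts$fn
  ev <- denom > 0
  data.frame(
    class = counts$names,
    id = counts$ids,
    PA = (counts$tp + counts$tn) / counts$n_pixels,
    Dice = ifelse(ev, 2 * counts$tp / (2 * counts$tp + counts$fp + counts$fn),
                  NA_real_),
    IoU = ifelse(ev, counts$tp / denom, NA_real_),
    evaluable = ev,
    row.names = NULL
  )
}

# Boundary pixel coordinates (rows of cbind(r, c)) of a binary mask:
# mask pixels with at least one 4-neighbour outside the mask (the image
# border counts as outside).
boundary_pixels <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  pad <- matrix(FALSE, H + 2, W + 2)
  pad[2:(H + 1), 2:(W + 1)] <- mask
  core <- pad[2:(H + 1), 2:(W + 1)]
  inside <- pad[1:H, 2:(W + 1)] & pad[3:(H + 2), 2:(W + 1)] &
    pad[2:(H + 1), 1:W] & pad[2:(H + 1), 3:(W + 2)]
  which(core & !inside, arr.ind = TRUE)
}

#' Average surface distance between two masks for one class
#'
#' Symmetric mean of nearest-boundary Euclidean distances (pixel units):
#' the sum over boundary pixels of each mask of the distance to the nearest
#' boundary pixel of the other mask, divided by the total number of boundary
#' pixels. Boundaries use 4-connectivity and pixel centres. Returns `NA`
#' (unevaluable) when the class is absent from the truth and the worst case
#' (the image diagonal) when the truth has the class but the prediction is
#' empty.
#'
#' @param pred,truth Equal-shaped integer label masks.
#' @param class_id Class id to evaluate.
#' @return ASD in pixels (0 for coincident masks).
#' @export
surface_distance <- function(pred, truth, class_id) {
  assert_that(all(dim(pred) == dim(truth)), "pred/truth shape mismatch")
  tb <- boundary_pixels(truth == class_id)
  if (nrow(tb) == 0) return(NA_real_)
  pb <- boundary_pixels(pred == class_id)
  if (nrow(pb) == 0) return(sqrt(nrow(pred)^2 + ncol(pred)^2))
  d2 <- outer(pb[, 1], tb[, 1], `-`)^2 + outer(pb[, 2], tb[, 2], `-`)^2
  (sum(sqrt(apply(d2, 1, min))) + sum(sqrt(apply(d2, 2, min)))) /
    (nrow(pb) + nrow(tb))
}

#' Macro mean over evaluable classes
#'
#' Unweighted arithmetic mean of a per-class metric over evaluable
#' foreground classes (the convention of the mIoU/mDice/mPA/mASD summary
#' metrics).
#'
#' @param values Per-class metric values.
#' @param flags Logical evaluability flags (`NA` values are also skipped).
#' @return Scalar mean.
#' @export
aggregate_macro <- function(values, flags = !is.na(values)) {
  keep <- flags & !is.na(values)
  assert_that(any(keep), "no evaluable classes to aggregate")
  mean(values[keep])
}

#' Per-class and macro metric report for a set of predictions
#'
#' IoU, Dice and PA are computed from confusion counts pooled over the whole
#' set per class (one number per class, as in per-structure results tables);
#' ASD is averaged over the images whose truth contains the class. The
#' `mean` row holds macro means over evaluable foreground classes.
#'
#' @param preds,truths Lists (or single masks) of equal-shaped label masks.
#' @param schema A [label_schema()].
#' @return A `metric_report` data frame: one row per foreground class plus a
#'   `"mean"` row, columns `IoU`, `Dice`, `PA`, `ASD`, `evaluable`.
#' @export
metric_report <- function(preds, truths, schema) {
  if (is.matrix(preds)) preds <- list(preds)
  if (is.matrix(truths)) truths <- list(truths)
  assert_that(length(preds) == length(truths) && length(preds) >= 1,
              "need equally many prediction and truth masks")
  counts <- pool_confusion(mapply(confusion_counts, preds, truths,
                                  MoreArgs = list(schema = schema),
                                  SIMPLIFY = FALSE))
  pcm <- per_class_metrics(counts)
  fg <- pcm$id >= 1
  asd <- vapply(pcm$id, function(cid) {
    if (cid == 0) return(NA_real_)
    vals <- mapply(function(p, t) surface_distance(p, t, cid), preds, truths)
    vals <- vals[!is.na(vals)]
    if (length(vals)) mean(vals) else NA_real_
  }, numeric(1))
  rep_df <- data.frame(class = pcm$class[fg], IoU = pcm$IoU[fg],
                       Dice = pcm$Dice[fg], PA = pcm$PA[fg],
                       ASD = asd[fg], evaluable = pcm$evaluable[fg],
                       row.names = NULL)
  mean_row <- data.frame(
    class = "mean",
    IoU = aggregate_macro(rep_df$IoU, rep_df$evaluable),
    Dice = aggregate_macro(rep_df$Dice, rep_df$evaluable),
    PA = aggregate_macro(rep_df$PA, rep_df$evaluable),
    ASD = aggregate_macro(rep_df$ASD),
    evaluable = TRUE
  )
  out <- rbind(rep_df, mean_row)
  class(out) <- c("metric_report", "data.frame")
  out
}

#' @export
print.metric_report <- function(x, digits = 3, ...) {
  df <- as.data.frame(x)
  for (cl in c("IoU", "Dice", "PA", "ASD")) df[[cl]] <- round(df[[cl]], digits)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Write a metric report as CSV and/or JSON
#' @param report A [metric_report()].
#' @param csv,json Output paths (either may be `NULL`).
#' @return `report`, invisibly.
#' @export
write_metric_report <- function(report, csv = NULL, json = NULL) {
  if (!is.null(csv)) {
    utils::write.csv(as.data.frame(report), csv, row.names = FALSE)
  }
  if (!is.null(json)) {
    jsonlite::write_json(as.data.frame(report), json, dataframe = "rows",
                         auto_unbox = TRUE, digits = NA, na = "null")
  }
  invisible(report)
}
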