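#' Jaccard index (intersection over union) of two binary masks
#'
#' Agreement between a predicted segmentation and a ground-truth
#' segmentation: shared area over combined area. Values above about 0.7 are
#' conventionally read as high coverage. Defined as 1 when both masks are
#' empty.
#'
#' @param a,b logical (or 0/1) matrices of identical shape.
#' @return numeric in [0, 1].
#' @export
jaccard_index <- function(a, b) {
  a <- as_pixels(a) > 0; b <- as_pixels(b) > 0
  if (!all(dim(a) == dim(b)))
    stop("mask shapes differ: ", paste(dim(a), collapse = "x"), " vs ",
         paste(dim(b), collapse = "x"))
  u <- sum(a | b)
  if (u == 0L) return(1)
  sum(a & b) / u
}

#' Object-level confusion counts at an 8-bit threshold
#'
#' An object is predicted compacted iff its \code{p8} strictly exceeds
#' \code{T}. Ground truth is matched by object identity (the analyst labels
#' the model's own outlines), so every object id must carry a label.
#'
#' @param gt named vector or data.frame (\code{id}, \code{class}) of
#'   ground-truth classes, "compacted"/"non_compacted".
#' @param objs \code{object_set} or data.frame with \code{id}, \code{p8}.
#' @param T integer threshold; -1 is the "select everything" sentinel.
#' @return list of class \code{confusion_counts}: TP, FP, TN, FN.
#' @export
confusion_at_threshold <- function(gt, objs, T) {
  tb <- if (inherits(objs, "object_set")) objs$table else objs
  if (!"p8" %in% names(tb)) stop("objects carry no p8")
  if (is.data.frame(gt)) gt <- setNames(gt$class, gt$id)
  cls <- gt[as.character(tb$id)]
  if (any(is.na(cls)))
    stop("unlabeled object id(s): ",
         paste(tb$id[is.na(cls)], collapse = ", "))
  pred_pos <- tb$p8 > T
  is_pos <- cls == "compacted"
  structure(list(
    TP = sum(pred_pos & is_pos), FP = sum(pred_pos & !is_pos),
    TN = sum(!pred_pos & !is_pos), FN = sum(!pred_pos & is_pos)
  ), class = "confusion_counts")
}

#' True- and false-positive rates from confusion counts
#'
#' TPR = TP/(TP+FN), the fraction of compacted thrombi recovered; FPR =
#' FP/(FP+TN), the fraction of non-compacted structures falsely selected.
#' A zero denominator yields NA (undefined) and such entries are excluded
#' from curve averaging.
#'
#' @param cc a \code{confusion_counts}.
#' @return named numeric vector \code{c(tpr, fpr)}, possibly NA.
#' @export
tpr_fpr <- function(cc) {
  tpr <- if (cc$TP + cc$FN > 0L) cc$TP / (cc$TP + cc$FN) else NA_real_
  fpr <- if (cc$FP + cc$TN > 0L) cc$FP / (cc$FP + cc$TN) else NA_real_
  c(tpr = tpr, fpr = fpr)
}

#' The standard 22-threshold sweep
#'
#' 22 probabilities evenly spanning 0.16 to 0.98, rendered to the 8-bit
#' scale (41 to 250).
#'
#' @return integer vector of length 22.
#' @export
paper_thresholds <- function() {
  as.integer(round_half_up(255 * seq(0.16, 0.98, length.out = 22L)))
}

#' Threshold-swept ROC from per-image confusion matrices
#'
#' For every image and every threshold, the object-level confusion matrix is
#' computed, TPR/FPR derived, and an averaged curve is formed as the
#' arithmetic mean of the per-image rates at each fixed threshold (undefined
#' rates excluded; the exclusion count is recorded).
#'
#' @param gt_list list of per-image ground-truth labels (named vector or
#'   data.frame per image).
#' @param obj_list list of per-image \code{object_set}s (or tables) with
#'   \code{p8}.
#' @param thresholds ascending integer thresholds (default
#'   \code{\link{paper_thresholds}}).
#' @return list of class \code{roc_curves}: \code{per_image} (data.frame:
#'   image, threshold, TP, FP, TN, FN, tpr, fpr), \code{averaged}
#'   (threshold, tpr, fpr, n_images), \code{n_excluded}.
#' @export
roc_sweep <- function(gt_list, obj_list, thresholds = paper_thresholds()) {
  stopifnot(length(gt_list) == length(obj_list), length(gt_list) >= 1L)
  if (is.unsorted(thresholds)) stop("thresholds must be sorted ascending")
  rows <- list()
  for (i in seq_along(obj_list)) {
    for (T in thresholds) {
      cc <- confusion_at_threshold(gt_list[[i]], obj_list[[i]], T)
      r <- tpr_fpr(cc)
      rows[[length(rows) + 1L]] <- data.frame(
        image = i, threshold = T, TP = cc$TP, FP = cc$FP, TN = cc$TN,
        FN = cc$FN, tpr = r[["tpr"]], fpr = r[["fpr"]])
    }
  }
  per_image <- do.call(rbind, rows)
  avg <- do.call(rbind, lapply(thresholds, function(T) {
    sub <- per_image[per_image$threshold == T, ]
    data.frame(threshold = T,
               tpr = mean(sub$tpr, na.rm = TRUE),
               fpr = mean(sub$fpr, na.rm = TRUE),
               n_images = sum(!is.na(sub$tpr) & !is.na(sub$fpr)))
  }))
  structure(list(per_image = per_image, averaged = avg,
                 n_excluded = sum(is.na(per_image$tpr)) +
                   sum(is.na(per_image$fpr))),
            class = "roc_curves")
}

#' Area under an averaged ROC curve
#'
#' Trapezoidal area over (FPR, TPR) with the curve closed at (0,0) and
#' (1,1) — the operating points reached at thresholds above the maximum and
#' below the minimum object probability.
#'
#' @param roc a \code{roc_curves} object or a data.frame with \code{tpr},
#'   \code{fpr}.
#' @return numeric AUC in [0, 1].
#' @export
roc_auc <- function(roc) {
  df <- if (inherits(roc, "roc_curves")) roc$averaged else roc
  pts <- rbind(c(0, 0), cbind(df$fpr, df$tpr), c(1, 1))
  pts <- pts[stats::complete.cases(pts), , drop = FALSE]
  o <- order(pts[, 1L], pts[, 2L])
  x <- pts[o, 1L]; y <- pts[o, 2L]
  sum(diff(x) * (head(y, -1L) + y[-1L]) / 2)
}
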