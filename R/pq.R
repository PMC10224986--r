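# ---- Panoptic Quality -----------------------------------------------------
#
# Strict-IoU matching and the RQ/SQ/PQ decomposition:
#   RQ = TP / (TP + FP/2 + FN/2)        (object-level F1)
#   SQ = sum(IoU of matched pairs) / TP (mean matched IoU)
#   PQ = SQ * RQ = sum(IoU) / (TP + FP/2 + FN/2)
# With the matching threshold at IoU > 0.5 every instance can belong to at
# most one pair, so no assignment step is needed.

new_match_result <- function(class_label, pairs, unmatched_gt, unmatched_pred) {
  structure(list(class_label = class_label,
                 pairs = pairs,
                 unmatched_gt = as.integer(unmatched_gt),
                 unmatched_pred = as.integer(unmatched_pred)),
            class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("<match_result> class %s: %d pairs, %d unmatched gt, %d unmatched pred\n",
              if (is.na(x$class_label)) "(any)" else x$class_label,
              nrow(x$pairs), length(x$unmatched_gt), length(x$unmatched_pred)))
  invisible(x)
}

empty_pairs <- function() {
  data.frame(gt_id = integer(0), pred_id = integer(0), iou = numeric(0))
}

# one strict-IoU match per class, from a precomputed pair table
match_class_strict <- function(pairs, gt_ids, pred_ids, class_label, threshold) {
  sub <- pairs[pairs$g %in% gt_ids & pairs$p %in% pred_ids & pairs$iou > threshold, ]
  matched <- data.frame(gt_id = sub$g, pred_id = sub$p, iou = sub$iou)
  new_match_result(class_label, matched,
                   setdiff(gt_ids, matched$gt_id),
                   setdiff(pred_ids, matched$pred_id))
}

#' Match predicted to ground-truth instances by strict IoU
#'
#' Pairs every ground-truth instance of `class_label` with the predicted
#' instance of the same class whose IoU strictly exceeds `threshold`.  At
#' thresholds >= 0.5 such a partner is necessarily unique, so the matching
#' needs no assignment procedure; a pair at IoU exactly equal to the
#' threshold is NOT matched.  Ambiguous-region pixels (union of both
#' scenes' masks) are removed from all instances before any overlap is
#' computed, and instances emptied by the removal are dropped.
#'
#' @param gt,pred `annotated_scene` objects of identical dimensions.
#' @param class_label the class to match (integer label).
#' @param threshold IoU threshold, >= 0.5 (strict inequality applied).
#' @return a `match_result` with `pairs` (gt_id, pred_id, iou) and the
#'   unmatched IDs of both scenes.
#' @export
match_by_iou <- function(gt, pred, class_label, threshold = 0.5) {
  if (threshold < 0.5)
    stop("IoU matching threshold below 0.5 would break match uniqueness",
         call. = FALSE)
  sc <- mask_ambiguous_pair(gt, pred)
  pairs <- pair_overlaps(sc$gt, sc$pred)
  match_class_strict(pairs,
                     scene_ids(sc$gt)[sc$gt$class_of == class_label],
                     scene_ids(sc$pred)[sc$pred$class_of == class_label],
                     class_label, threshold)
}

#' Per-class, per-image PQ from a match result
#'
#' Object counts come from the match (`tp` pairs, `fp` unmatched
#' predictions, `fn` unmatched ground truths).  When no objects of the
#' class exist on either side all three quality values are undefined
#' (`NA`); when tp = 0 but fp + fn > 0, RQ and PQ are 0 and SQ is
#' undefined.
#'
#' @param match a `match_result` produced at threshold >= 0.5.
#' @return a list of class `class_image_pq` with fields `tp`, `fp`, `fn`,
#'   `iou_sum`, `rq`, `sq`, `pq`.
#' @export
pq_class_image <- function(match) {
  tp <- nrow(match$pairs)
  fp <- length(match$unmatched_pred)
  fn <- length(match$unmatched_gt)
  iou_sum <- sum(match$pairs$iou)
  denom <- tp + 0.5 * (fp + fn)
  if (denom == 0) {
    rq <- sq <- pq <- NA_real_
  } else {
    rq <- tp / denom
    pq <- iou_sum / denom
    sq <- if (tp > 0) iou_sum / tp else NA_real_
  }
  structure(list(class_label = match$class_label, tp = tp, fp = fp, fn = fn,
                 iou_sum = iou_sum, rq = rq, sq = sq, pq = pq),
            class = "class_image_pq")
}

#' @export
print.class_image_pq <- function(x, ...) {
  cat(sprintf("<class_image_pq> tp=%d fp=%d fn=%d rq=%.4f sq=%.4f pq=%.4f\n",
              x$tp, x$fp, x$fn, x$rq, x$sq, x$pq))
  invisible(x)
}

#' Per-(image, class) PQ table for a dataset
#'
#' One row per image and per class present in that image's ground truth or
#' prediction (classes absent from both are skipped).  This is the raw
#' material for both aggregation schemes.
#'
#' @param gts,preds equal-length, index-aligned lists of `annotated_scene`.
#' @param threshold IoU matching threshold (>= 0.5, strict).
#' @return data.frame with columns image, class, tp, fp, fn, iou_sum, rq,
#'   sq, pq.
#' @export
pq_table <- function(gts, preds, threshold = 0.5) {
  stopifnot(length(gts) == length(preds))
  if (!length(gts)) stop("empty dataset", call. = FALSE)
  rows <- list()
  for (i in seq_along(gts)) {
    sc <- mask_ambiguous_pair(gts[[i]], preds[[i]])
    pairs <- pair_overlaps(sc$gt, sc$pred)
    classes <- sort(union(scene_classes(sc$gt), scene_classes(sc$pred)))
    for (cl in classes) {
      m <- match_class_strict(pairs,
                              scene_ids(sc$gt)[sc$gt$class_of == cl],
                              scene_ids(sc$pred)[sc$pred$class_of == cl],
                              cl, threshold)
      q <- pq_class_image(m)
      rows[[length(rows) + 1L]] <-
        data.frame(image = i, class = cl, tp = q$tp, fp = q$fp, fn = q$fn,
                   iou_sum = q$iou_sum, rq = q$rq, sq = q$sq, pq = q$pq)
    }
  }
  if (!length(rows))
    return(data.frame(image = integer(0), class = integer(0), tp = integer(0),
                      fp = integer(0), fn = integer(0), iou_sum = numeric(0),
                      rq = numeric(0), sq = numeric(0), pq = numeric(0)))
  do.call(rbind, rows)
}

#' Aggregate PQ over a dataset (both published schemes)
#'
#' Computes the image-averaged aggregation `aPQ` (per image, PQ_i is the
#' mean of the per-class PQ over the classes present in that image; aPQ is
#' the mean over images) and the class-pooled aggregation `mPQ` (per class,
#' TP/FP/FN and IoU sums are pooled over all images before computing PQ_c;
#' mPQ is the mean over classes).  A class present in exactly one of
#' ground truth or prediction contributes PQ = 0; a class absent from both
#' sides of an image is excluded from that image's average.  Images with no
#' instances at all are excluded from `n` with a warning, and a pooled
#' class with no objects anywhere contributes 0 to mPQ with a warning.
#'
#' @inheritParams pq_table
#' @param classes optional integer vector fixing the class universe for
#'   mPQ; defaults to all classes seen in the dataset.
#' @return an `aggregate_pq` object with fields `apq`, `mpq`, `per_image`,
#'   `per_class_pooled`, `table`, `n_images`, `classes`.
#' @export
aggregate_pq <- function(gts, preds, threshold = 0.5, classes = NULL) {
  tab <- pq_table(gts, preds, threshold)
  per_image <- vapply(seq_along(gts), function(i) {
    pqs <- tab$pq[tab$image == i]
    if (!length(pqs)) NA_real_ else mean(pqs)
  }, numeric(1))
  if (anyNA(per_image)) {
    warning(sprintf("%d image(s) with no instances excluded from aPQ",
                    sum(is.na(per_image))))
  }
  apq <- mean(per_image, na.rm = TRUE)

  if (is.null(classes)) classes <- sort(unique(tab$class))
  per_class <- vapply(classes, function(cl) {
    sub <- tab[tab$class == cl, ]
    denom <- sum(sub$tp) + 0.5 * (sum(sub$fp) + sum(sub$fn))
    if (denom == 0) {
      warning(sprintf("class %s has no objects in the dataset; PQ_c coerced to 0", cl))
      return(0)
    }
    sum(sub$iou_sum) / denom
  }, numeric(1))
  mpq <- mean(per_class)

  structure(list(apq = apq, mpq = mpq,
                 per_image = per_image,
                 per_class_pooled = setNames(per_class, classes),
                 table = tab, n_images = sum(!is.na(per_image)),
                 classes = classes),
            class = "aggregate_pq")
}

#' @export
print.aggregate_pq <- function(x, ...) {
  cat(sprintf("<aggregate_pq> aPQ = %.4f (n = %d images), mPQ = %.4f (m = %d classes)\n",
              x$apq, x$n_images, x$mpq, length(x$classes)))
  invisible(x)
}

#' Image-averaged aggregate PQ (aPQ)
#'
#' Convenience wrapper around [aggregate_pq()]; both aggregations are
#' computed and returned, `$apq` being the headline value.
#' @inheritParams aggregate_pq
#' @return an `aggregate_pq` object.
#' @export
apq <- function(gts, preds, threshold = 0.5, classes = NULL)
  aggregate_pq(gts, preds, threshold, classes)

#' Class-pooled aggregate PQ (mPQ)
#'
#' Convenience wrapper around [aggregate_pq()]; both aggregations are
#' computed and returned, `$mpq` being the headline value.
#' @inheritParams aggregate_pq
#' @return an `aggregate_pq` object.
#' @export
mpq <- function(gts, preds, threshold = 0.5, classes = NULL)
  aggregate_pq(gts, preds, threshold, classes)

#' Evaluate a prediction set against ground truth
#'
#' Runs strict-IoU PQ evaluation plus the separated metrics the package
#' recommends alongside it: class-agnostic detection (centroid matching),
#' detection F1, balanced accuracy on the detected nuclei, and the median
#' Hausdorff distance over matched pairs.
#'
#' @inheritParams aggregate_pq
#' @param radius tolerance radius in pixels for the class-agnostic
#'   centroid matcher used by the separated detection metrics.
#' @return list with `pq` (an `aggregate_pq`), `per_class_image` rows,
#'   `detection_f1`, `balanced_accuracy`, `median_hd`, `confusion`.
#' @export
evaluate_dataset <- function(gts, preds, threshold = 0.5, classes = NULL,
                             radius = 15) {
  agg <- aggregate_pq(gts, preds, threshold, classes)
  conf <- NULL
  hds <- numeric(0)
  for (i in seq_along(gts)) {
    m <- match_by_centroid(gts[[i]], preds[[i]], radius = radius)
    ci <- confusion_isc(gts[[i]], preds[[i]], m, classes = agg$classes)
    conf <- if (is.null(conf)) ci else conf + ci
    if (nrow(m$pairs))
      hds <- c(hds, pair_hausdorff(gts[[i]], preds[[i]], m$pairs))
  }
  ba <- if (sum(conf[-1, -1]) > 0) balanced_accuracy(conf) else NA_real_
  list(pq = agg, per_class_image = agg$table,
       detection_f1 = detection_f1(conf),
       balanced_accuracy = ba,
       median_hd = if (length(hds)) median(hds) else NA_real_,
       confusion = conf)
}
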