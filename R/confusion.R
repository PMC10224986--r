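# ---- alternative matching rules and separated metrics ---------------------

# greedy one-to-one assignment from a candidate table ordered best-first;
# cand must have columns g, p (already sorted)
greedy_assign <- function(cand) {
  used_g <- integer(0); used_p <- integer(0); keep <- logical(nrow(cand))
  for (k in seq_len(nrow(cand))) {
    if (!(cand$g[k] %in% used_g) && !(cand$p[k] %in% used_p)) {
      keep[k] <- TRUE
      used_g <- c(used_g, cand$g[k]); used_p <- c(used_p, cand$p[k])
    }
  }
  cand[keep, , drop = FALSE]
}

#' Match instances by any overlap, largest IoU first
#'
#' Class-agnostic matching in the loosest sense: every overlapping
#' (ground-truth, prediction) pair is a candidate; when an object has
#' several candidates the pair with the largest IoU wins, conflicts being
#' resolved greedily in descending IoU order (ties broken by gt then pred
#' ID).  The result is one-to-one.
#'
#' @param gt,pred `annotated_scene` objects of identical dimensions.
#' @return a class-agnostic `match_result` (class_label = NA).
#' @export
match_by_overlap <- function(gt, pred) {
  sc <- mask_ambiguous_pair(gt, pred)
  pairs <- as.data.frame(pair_overlaps(sc$gt, sc$pred))
  pairs <- pairs[order(-pairs$iou, pairs$g, pairs$p), , drop = FALSE]
  chosen <- greedy_assign(pairs)
  new_match_result(NA_integer_,
                   data.frame(gt_id = chosen$g, pred_id = chosen$p, iou = chosen$iou),
                   setdiff(scene_ids(sc$gt), chosen$g),
                   setdiff(scene_ids(sc$pred), chosen$p))
}

#' Match instances by greedy minimal centroid distance
#'
#' Candidate pairs are all (ground-truth, prediction) pairs whose centroid
#' distance is within the tolerance `radius`; candidates are sorted by
#' ascending distance (ties broken by gt then pred ID) and assigned
#' greedily, removing every other candidate of an assigned object.  The
#' default radius of 15 px at 0.25 um/px is on the order of a typical
#' nucleus radius.
#'
#' @inheritParams match_by_overlap
#' @param radius tolerance radius in pixels (> 0).
#' @return a class-agnostic `match_result` whose `pairs` carry the matched
#'   pair IoU (0 if disjoint) and a `distance` column.
#' @export
match_by_centroid <- function(gt, pred, radius = 15) {
  if (radius <= 0) stop("`radius` must be positive", call. = FALSE)
  sc <- mask_ambiguous_pair(gt, pred)
  cg <- scene_centroids(sc$gt); cp <- scene_centroids(sc$pred)
  gid <- scene_ids(sc$gt); pid <- scene_ids(sc$pred)
  if (!length(gid) || !length(pid)) {
    return(new_match_result(NA_integer_,
                            cbind(empty_pairs(), distance = numeric(0)),
                            gid, pid))
  }
  d <- sqrt(outer(cg[, 1], cp[, 1], `-`)^2 + outer(cg[, 2], cp[, 2], `-`)^2)
  idx <- which(d <= radius, arr.ind = TRUE)
  cand <- data.frame(g = gid[idx[, 1]], p = pid[idx[, 2]],
                     distance = d[idx])
  cand <- cand[order(cand$distance, cand$g, cand$p), , drop = FALSE]
  chosen <- greedy_assign(cand)
  ious <- if (nrow(chosen)) {
    ov <- pair_overlaps(sc$gt, sc$pred)
    key <- paste(ov$g, ov$p)
    v <- ov$iou[match(paste(chosen$g, chosen$p), key)]
    ifelse(is.na(v), 0, v)
  } else numeric(0)
  new_match_result(NA_integer_,
                   data.frame(gt_id = chosen$g, pred_id = chosen$p,
                              iou = ious, distance = chosen$distance),
                   setdiff(gid, chosen$g), setdiff(pid, chosen$p))
}

#' Object-level confusion matrix with a background row and column
#'
#' For an m-class problem the matrix is (m+1) x (m+1): row = ground-truth
#' class, column = predicted class, with index 1 ("background") holding
#' missed detections (column) and spurious detections (row).  The top-left
#' cell is structurally zero — there are no countable correctly-predicted
#' "background objects" — and is flagged via the `"not_countable"`
#' attribute.  The sum of each class row is fixed by the ground truth, so
#' it is invariant to the prediction; the total sum is not (the background
#' row depends on the false detections).
#'
#' @param gt,pred `annotated_scene` objects.
#' @param match a class-agnostic `match_result` pairing the two scenes.
#' @param classes optional integer vector fixing the class universe.
#' @return integer matrix of class `confusion_isc` with labelled dimnames.
#' @export
confusion_isc <- function(gt, pred, match, classes = NULL) {
  if (is.null(classes))
    classes <- sort(union(scene_classes(gt), scene_classes(pred)))
  m <- length(classes)
  lab <- c("background", as.character(classes))
  counts <- matrix(0L, m + 1L, m + 1L, dimnames = list(gt = lab, pred = lab))
  cls_idx <- function(cl) match(cl, classes) + 1L
  if (nrow(match$pairs)) {
    a <- cls_idx(gt$class_of[as.character(match$pairs$gt_id)])
    b <- cls_idx(pred$class_of[as.character(match$pairs$pred_id)])
    for (k in seq_along(a)) counts[a[k], b[k]] <- counts[a[k], b[k]] + 1L
  }
  for (id in match$unmatched_gt) {
    a <- cls_idx(gt$class_of[as.character(id)])
    counts[a, 1L] <- counts[a, 1L] + 1L
  }
  for (id in match$unmatched_pred) {
    b <- cls_idx(pred$class_of[as.character(id)])
    counts[1L, b] <- counts[1L, b] + 1L
  }
  structure(counts, not_countable = c(1L, 1L), class = c("confusion_isc", "matrix", "array"))
}

#' Detection F1 on a single "nucleus vs background" class
#'
#' Collapses all nucleus classes into one foreground class and scores
#' detection alone: F1 = 2 TP / (2 TP + FP + FN) over objects, where TP is
#' any matched pair regardless of class agreement.
#'
#' @param conf an object-level confusion matrix as built by
#'   [confusion_isc()] (plain (m+1) x (m+1) matrices are accepted).
#' @return a fraction in \[0, 1\].
#' @export
detection_f1 <- function(conf) {
  conf <- unclass(conf)
  tp <- sum(conf[-1, -1])
  fn <- sum(conf[-1, 1])
  fp <- sum(conf[1, -1])
  if (tp + fp + fn == 0) return(NA_real_)
  2 * tp / (2 * tp + fp + fn)
}

#' Balanced accuracy on the detected nuclei
#'
#' Mean per-class recall over the m x m submatrix of matched objects only
#' (missed and spurious detections are the detection metric's business,
#' not the classifier's).  Ground-truth classes with no matched object are
#' excluded with a warning.
#'
#' @inheritParams detection_f1
#' @return a fraction in \[0, 1\].
#' @export
balanced_accuracy <- function(conf) {
  conf <- unclass(conf)
  sub <- conf[-1, -1, drop = FALSE]
  if (sum(sub) == 0)
    stop("balanced accuracy is undefined without matched objects", call. = FALSE)
  totals <- rowSums(sub)
  if (any(totals == 0))
    warning(sprintf("%d class(es) with no matched objects excluded from balanced accuracy",
                    sum(totals == 0)))
  keep <- totals > 0
  mean(diag(sub)[keep] / totals[keep])
}

#' Rank methods per metric and sum the ranks
#'
#' The rank-sum aggregation used by segmentation challenges: each metric
#' column is ranked across methods (rank 1 = best, respecting the metric's
#' orientation; ties receive mid-ranks) and each method's ranks are summed.
#' Lower rank sums are better.
#'
#' @param scores numeric matrix, methods in rows, metrics in columns.
#' @param higher_is_better logical vector, one flag per metric.
#' @return a `rank_table` list with `scores`, `ranks`, `rank_sums`.
#' @export
sum_of_ranks <- function(scores, higher_is_better) {
  scores <- as.matrix(scores)
  if (nrow(scores) < 2 || ncol(scores) < 1)
    stop("need at least two methods and one metric", call. = FALSE)
  if (length(higher_is_better) != ncol(scores))
    stop("one orientation flag per metric is required", call. = FALSE)
  if (anyNA(scores)) stop("missing scores are not imputed", call. = FALSE)
  ranks <- vapply(seq_len(ncol(scores)), function(j) {
    x <- scores[, j]
    rank(if (higher_is_better[j]) -x else x, ties.method = "average")
  }, numeric(nrow(scores)))
  dimnames(ranks) <- dimnames(scores)
  structure(list(scores = scores, ranks = ranks, rank_sums = rowSums(ranks)),
            class = "rank_table")
}

#' @export
print.rank_table <- function(x, ...) {
  cat("<rank_table> rank sums (lower is better):\n")
  print(sort(x$rank_sums))
  invisible(x)
}
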