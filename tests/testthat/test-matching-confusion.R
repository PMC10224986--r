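test_that("any-overlap matching picks the largest-IoU partner", {
  g <- scene_from_masks(list(rect_mask(10, 24, 1, 1, 1, 20)), 1)   # 20 px bar
  p <- scene_from_masks(list(rect_mask(10, 24, 1, 1, 1, 6),        # IoU 0.3
                             rect_mask(10, 24, 1, 1, 7, 18)), c(1, 1))  # IoU 0.6
  m <- match_by_overlap(g, p)
  expect_equal(m$pairs$gt_id, 1L)
  expect_equal(m$pairs$pred_id, 2L)
  expect_equal(m$pairs$iou, 0.6)
  expect_equal(m$unmatched_pred, 1L)

  # disjoint scenes: no pairs
  d1 <- scene_from_masks(list(rect_mask(10, 10, 1, 2, 1, 2)), 1)
  d2 <- scene_from_masks(list(rect_mask(10, 10, 8, 9, 8, 9)), 1)
  expect_equal(nrow(match_by_overlap(d1, d2)$pairs), 0)
})

test_that("any-overlap matching equals greedy exhaustive search on random scenes", {
  set.seed(17)
  for (rep in 1:15) {
    gt <- random_boxes_scene(n = 5L)
    pred <- degrade(gt, degradation_spec(jitter_px = 2))$scene
    m <- match_by_overlap(gt, pred)
    # independent greedy reference over the full IoU matrix
    cand <- NULL
    for (g in scene_ids(gt)) for (p in scene_ids(pred)) {
      v <- iou(instance_mask(gt, g), instance_mask(pred, p))
      if (v > 0) cand <- rbind(cand, data.frame(g = g, p = p, iou = v))
    }
    pairs <- NULL
    if (!is.null(cand)) {
      cand <- cand[order(-cand$iou, cand$g, cand$p), ]
      while (nrow(cand)) {
        pairs <- rbind(pairs, cand[1, ])
        cand <- cand[cand$g != cand$g[1] & cand$p != cand$p[1], , drop = FALSE]
      }
    }
    if (is.null(pairs)) {
      expect_equal(nrow(m$pairs), 0)
    } else {
      o <- order(pairs$g)
      got <- m$pairs[order(m$pairs$gt_id), ]
      expect_equal(got$gt_id, pairs$g[o])
      expect_equal(got$pred_id, pairs$p[o])
    }
    expect_false(any(duplicated(m$pairs$gt_id)))
    expect_false(any(duplicated(m$pairs$pred_id)))
  }
})

test_that("centroid matching assigns greedily in order of closeness", {
  px <- function(r, c) mask_from_coords(12, 12, c(r, c))
  # distances: d(g1,p1)=2, d(g1,p2)=1, d(g2,p1)=5, d(g2,p2)=2
  g <- scene_from_masks(list(px(1, 6), px(1, 3)), c(1, 1))
  p <- scene_from_masks(list(px(1, 8), px(1, 5)), c(1, 1))
  m <- match_by_centroid(g, p, radius = 10)
  o <- order(m$pairs$gt_id)
  expect_equal(m$pairs$gt_id[o], c(1L, 2L))
  expect_equal(m$pairs$pred_id[o], c(2L, 1L))   # g1 takes the closer p2
  expect_equal(sort(m$pairs$distance), c(1, 5))

  # beyond the radius nothing is matched
  far <- match_by_centroid(g, scene_from_masks(list(px(12, 12)), 1), radius = 3)
  expect_equal(nrow(far$pairs), 0)
  expect_equal(far$unmatched_gt, c(1L, 2L))

  # identical scenes match at distance zero
  set.seed(2)
  sc <- random_boxes_scene()
  self <- match_by_centroid(sc, sc, radius = 5)
  expect_equal(nrow(self$pairs), length(scene_ids(sc)))
  expect_equal(self$pairs$distance, rep(0, nrow(self$pairs)))
  expect_equal(self$pairs$iou, rep(1, nrow(self$pairs)))
})

test_that("the ISC confusion matrix books matched and unmatched objects", {
  masks <- list(rect_mask(20, 20, 1, 3, 1, 3), rect_mask(20, 20, 6, 8, 1, 3),
                rect_mask(20, 20, 11, 13, 1, 3))
  gt <- scene_from_masks(masks, c(1, 2, 3))
  conf <- confusion_isc(gt, gt, match_by_overlap(gt, gt))
  expect_equal(unclass(conf), diag(c(0, 1, 1, 1)), ignore_attr = TRUE)

  # a macrophage detected but classified epithelial: one count at that cell
  gt2 <- scene_from_masks(masks[1:2], c(2, 1))     # classes: 1 epithelial-ish, 2 macro
  pr2 <- scene_from_masks(masks[1:2], c(1, 1))
  conf2 <- confusion_isc(gt2, pr2, match_by_overlap(gt2, pr2), classes = 1:2)
  expect_equal(conf2["2", "1"], 1L, ignore_attr = TRUE)
  # under per-class PQ this same event is an FP for class 1 and an FN for class 2
  tab <- pq_table(list(gt2), list(pr2))
  expect_equal(tab$fp[tab$class == 1], 1)
  expect_equal(tab$fn[tab$class == 2], 1)
})

test_that("class rows of the confusion matrix are fixed by the ground truth", {
  set.seed(4)
  gt <- random_boxes_scene(n = 8L, n_classes = 3L)
  gt_counts <- table(factor(gt$class_of, levels = 1:3))
  confs <- lapply(c(11, 22), function(s) {
    pred <- degrade(gt, degradation_spec(dropout_rate = 0.3, misclass_rate = 0.3,
                                         spurious_rate = 2), seed = s)$scene
    confusion_isc(gt, pred, match_by_overlap(gt, pred), classes = 1:3)
  })
  for (conf in confs)
    expect_equal(unname(rowSums(conf)[-1]), as.vector(gt_counts))
  # the total sum differs when the predictors hallucinate different numbers
  # of objects, unlike a panoptic-segmentation style class-only matrix
  totals <- vapply(confs, sum, 1)
  fps <- vapply(confs, function(x) sum(x[1, ]), 1)
  expect_equal(totals, sum(gt_counts) + fps)
})

test_that("detection F1 collapses classes and ignores labels", {
  conf <- matrix(c(0, 1, 0,
                   0, 1, 1,
                   1, 0, 1), 3, 3, byrow = TRUE)
  # tp = 3 matched, fp = 1 (background row), fn = 1 (background column)
  expect_equal(detection_f1(conf), 2 * 3 / (2 * 3 + 1 + 1))
  # permuting class labels leaves it unchanged
  perm <- conf[c(1, 3, 2), c(1, 3, 2)]
  expect_equal(detection_f1(perm), detection_f1(conf))
  # simple worked case: 2 matched, 1 unmatched pred, 1 unmatched gt
  conf2 <- matrix(c(0, 1, 0,
                    1, 2, 0,
                    0, 0, 0), 3, 3, byrow = TRUE)
  expect_equal(detection_f1(conf2), 2 / 3)
  # zero detections on a non-empty ground truth
  conf3 <- matrix(c(0, 0, 2, 0), 2, 2, byrow = TRUE)
  expect_equal(detection_f1(conf3), 0)
})

test_that("balanced accuracy is mean per-class recall over matched objects", {
  conf <- rbind(c(0, 0, 0), c(0, 3, 1), c(0, 2, 2))
  expect_equal(balanced_accuracy(conf), 0.625)
  # diagonal submatrix: 1; a fully misclassified class contributes 0
  expect_equal(balanced_accuracy(rbind(c(0, 0, 0), c(0, 4, 0), c(0, 0, 2))), 1)
  expect_equal(balanced_accuracy(rbind(c(0, 0, 0), c(0, 0, 3), c(0, 0, 2))),
               mean(c(0, 1)))
  # relabelling invariance
  perm <- conf[c(1, 3, 2), c(1, 3, 2)]
  expect_equal(balanced_accuracy(perm), balanced_accuracy(conf))
  # undefined without matches; unmatched-only classes excluded with warning
  expect_error(balanced_accuracy(rbind(c(0, 1), c(2, 0))), "undefined")
  expect_warning(balanced_accuracy(rbind(c(0, 0, 0), c(0, 2, 0), c(2, 0, 0))),
                 "excluded")
})

test_that("sum of ranks aggregates metric ranks with mid-rank ties", {
  scores <- rbind(A = c(0.9, 5, 0.7), B = c(0.8, 3, 0.7), C = c(0.7, 4, 0.9))
  rt <- sum_of_ranks(scores, higher_is_better = c(TRUE, FALSE, TRUE))
  expect_equal(rt$rank_sums, c(A = 6.5, B = 5.5, C = 6))
  expect_equal(unname(rt$ranks[, 1]), c(1, 2, 3))

  # a dominating method collects rank 1 everywhere
  dom <- rbind(X = c(1, 1), Y = c(0.5, 0.2), Z = c(0.1, 0.6))
  expect_equal(sum_of_ranks(dom, c(TRUE, TRUE))$rank_sums[["X"]], 2)
  # two methods each best at one metric tie overall
  sym <- rbind(M1 = c(1, 0), M2 = c(0, 1))
  expect_equal(unname(sum_of_ranks(sym, c(TRUE, TRUE))$rank_sums), c(3, 3))
  expect_error(sum_of_ranks(rbind(c(1, NA), c(0, 1)), c(TRUE, TRUE)), "missing")
  expect_error(sum_of_ranks(rbind(c(1, 2)), TRUE), "two methods")
})
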