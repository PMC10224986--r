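test_that("strict IoU matching rejects weak overlaps and exact-threshold ties", {
  # one gt object, one prediction at IoU 0.2: both stay unmatched
  g <- scene_from_masks(list(rect_mask(20, 20, 1, 2, 1, 10)), 1)
  p <- scene_from_masks(list(rect_mask(20, 20, 2, 5, 1, 10)), 1)
  m <- match_by_iou(g, p, 1)
  expect_equal(nrow(m$pairs), 0)
  expect_equal(m$unmatched_gt, 1L)
  expect_equal(m$unmatched_pred, 1L)

  # IoU exactly 0.5 is NOT a match (strict inequality)
  g2 <- scene_from_masks(list(mask_from_coords(5, 5, c(1, 1, 1, 2))), 1)
  p2 <- scene_from_masks(list(mask_from_coords(5, 5, c(1, 1))), 1)
  m2 <- match_by_iou(g2, p2, 1)
  expect_equal(nrow(m2$pairs), 0)

  # identical scenes: everything matched at IoU 1
  set.seed(5)
  sc <- random_boxes_scene()
  for (cl in scene_classes(sc)) {
    mm <- match_by_iou(sc, sc, cl)
    expect_equal(mm$pairs$iou, rep(1, nrow(mm$pairs)))
    expect_length(mm$unmatched_gt, 0)
  }

  expect_error(match_by_iou(g, p, 1, threshold = 0.3), "uniqueness")
})

test_that("matching is unique and agrees with a brute-force all-pairs matcher", {
  set.seed(99)
  for (rep in 1:30) {
    gt <- random_boxes_scene(n = 5L)
    pred <- degrade(gt, degradation_spec(dropout_rate = 0.2, jitter_px = 1,
                                         misclass_rate = 0.2))$scene
    pairs <- do.call(rbind, lapply(scene_classes(gt), function(cl)
      match_by_iou(gt, pred, cl)$pairs))
    expect_false(any(duplicated(pairs$gt_id)))
    expect_false(any(duplicated(pairs$pred_id)))
    bf <- bf_match_pairs(gt, pred)
    if (is.null(bf)) {
      expect_equal(nrow(pairs), 0)
    } else {
      o <- order(bf$gt_id)
      expect_equal(pairs[order(pairs$gt_id), ], bf[o, ], ignore_attr = TRUE)
    }
  }
})

test_that("per-class-image PQ follows the printed formula and edge cases", {
  # ious 0.8 and 0.9 matched, one unmatched prediction
  masks_g <- list(rect_mask(12, 24, 1, 1, 1, 18),   # 18 px bar
                  rect_mask(12, 24, 5, 5, 1, 19))   # 19 px bar
  masks_p <- list(rect_mask(12, 24, 1, 1, 3, 20),   # IoU 16/20 = 0.8
                  rect_mask(12, 24, 5, 5, 2, 20),   # IoU 18/20 = 0.9
                  rect_mask(12, 24, 10, 10, 1, 5))  # unmatched
  g <- scene_from_masks(masks_g, c(1, 1))
  p <- scene_from_masks(masks_p, c(1, 1, 1))
  q <- pq_class_image(match_by_iou(g, p, 1))
  expect_equal(q$rq, 0.8)
  expect_equal(q$sq, 0.85)
  expect_equal(q$pq, 0.68)

  # perfect prediction
  qp <- pq_class_image(match_by_iou(g, g, 1))
  expect_equal(c(qp$rq, qp$sq, qp$pq), c(1, 1, 1))

  # class present in gt, zero predictions: RQ = PQ = 0, SQ undefined
  empty <- annotated_scene(matrix(0L, 12, 24), integer(0))
  q0 <- pq_class_image(match_by_iou(g, empty, 1))
  expect_equal(q0$pq, 0)
  expect_equal(q0$rq, 0)
  expect_true(is.na(q0$sq))

  # no objects on either side: all undefined
  qe <- pq_class_image(match_by_iou(empty, empty, 1))
  expect_true(all(is.na(c(qe$rq, qe$sq, qe$pq))))
})

test_that("PQ decomposes as RQ x SQ whenever matches exist", {
  set.seed(21)
  for (rep in 1:20) {
    gt <- random_boxes_scene(n = 6L)
    pred <- degrade(gt, degradation_spec(dropout_rate = 0.15, jitter_px = 1))$scene
    tab <- pq_table(list(gt), list(pred))
    with_tp <- tab[tab$tp > 0, ]
    expect_equal(with_tp$pq, with_tp$rq * with_tp$sq, tolerance = 1e-12)
  }
})

test_that("a three-image toy dataset reproduces hand-computed aPQ and mPQ", {
  # classes: 1 = blue, 2 = orange
  g1 <- scene_from_masks(list(rect_mask(20, 20, 1, 4, 1, 5),
                              rect_mask(20, 20, 8, 11, 1, 5),
                              rect_mask(20, 20, 15, 18, 1, 5)), c(1, 1, 2))
  p1 <- scene_from_masks(list(rect_mask(20, 20, 1, 4, 1, 5),     # IoU 1
                              rect_mask(20, 20, 8, 11, 2, 6),    # IoU 2/3
                              rect_mask(20, 20, 15, 18, 1, 5)),  # IoU 1
                         c(1, 1, 2))
  g2 <- scene_from_masks(list(rect_mask(20, 20, 1, 2, 1, 10),
                              rect_mask(20, 20, 10, 11, 1, 10)), c(1, 2))
  p2 <- scene_from_masks(list(rect_mask(20, 20, 2, 5, 1, 10)), 1)  # IoU 0.2
  g3 <- scene_from_masks(list(rect_mask(20, 20, 1, 4, 1, 5),
                              rect_mask(20, 20, 10, 13, 1, 5)), c(2, 1))
  p3 <- scene_from_masks(list(rect_mask(20, 20, 1, 4, 1, 5),
                              rect_mask(20, 20, 10, 13, 1, 5)), c(2, 2))

  agg <- aggregate_pq(list(g1, g2, g3), list(p1, p2, p3))
  # PQ_1 = ((1 + 2/3)/2 + 1)/2 = 11/12 ; PQ_2 = 0 ; PQ_3 = (0 + 2/3)/2 = 1/3
  expect_equal(agg$per_image, c(11 / 12, 0, 1 / 3))
  expect_equal(agg$apq, 5 / 12)
  # pooled: class 1 -> (5/3)/3.5 = 10/21 ; class 2 -> 2/3
  expect_equal(unname(agg$per_class_pooled), c(10 / 21, 2 / 3))
  expect_equal(agg$mpq, 4 / 7)
})

test_that("aPQ equals mPQ on a single image containing every class", {
  set.seed(31)
  gt <- random_boxes_scene(n = 8L, n_classes = 3L)
  pred <- degrade(gt, degradation_spec(jitter_px = 1))$scene
  agg <- aggregate_pq(list(gt), list(pred))
  if (setequal(scene_classes(gt), union(scene_classes(gt), scene_classes(pred))))
    expect_equal(agg$apq, agg$mpq)
})

test_that("pooled mPQ counts equal the sums of per-image counts", {
  set.seed(77)
  gts <- replicate(5, random_boxes_scene(n = 5L), simplify = FALSE)
  preds <- lapply(gts, function(g)
    degrade(g, degradation_spec(dropout_rate = 0.2, jitter_px = 1))$scene)
  tab <- pq_table(gts, preds)
  agg <- aggregate_pq(gts, preds)
  for (cl in agg$classes) {
    sub <- tab[tab$class == cl, ]
    denom <- sum(sub$tp) + 0.5 * (sum(sub$fp) + sum(sub$fn))
    expect_equal(unname(agg$per_class_pooled[as.character(cl)]),
                 sum(sub$iou_sum) / denom)
  }
})

test_that("adding a false positive never increases RQ, PQ, aPQ or mPQ", {
  set.seed(55)
  gt <- random_boxes_scene(n = 6L)
  pred <- degrade(gt, degradation_spec(jitter_px = 1))$scene
  base <- aggregate_pq(list(gt), list(pred))
  # plant a spurious 3x3 box on free background of the same class
  map <- pred$instance_map
  free <- which(map == 0L & gt$instance_map == 0L)
  spot <- arrayInd(free[length(free) %/% 2], dim(map))
  r <- min(spot[1], nrow(map) - 3L); c <- min(spot[2], ncol(map) - 3L)
  reg <- map[r:(r + 2), c:(c + 2)]
  if (all(reg == 0L)) {
    map[r:(r + 2), c:(c + 2)] <- max(map) + 1L
    cl <- pred$class_of[1]
    worse <- annotated_scene(map, c(pred$class_of,
                                    stats::setNames(cl, max(map))))
    agg <- aggregate_pq(list(gt), list(worse))
    expect_lte(agg$apq, base$apq)
    expect_lte(agg$mpq, base$mpq)
    tab0 <- pq_table(list(gt), list(pred))
    tab1 <- pq_table(list(gt), list(worse))
    row0 <- tab0[tab0$class == cl, ]
    row1 <- tab1[tab1$class == cl, ]
    expect_lte(row1$rq, row0$rq)
    expect_lte(row1$pq, row0$pq)
  }
})

test_that("wrong-class detection is penalized harder than a missed detection", {
  # gt: two class-1 and two class-2 objects; the prediction is perfect except
  # for one class-1 target, either perfectly segmented but labelled class 2,
  # or absent
  masks <- list(rect_mask(30, 30, 1, 4, 1, 4), rect_mask(30, 30, 1, 4, 10, 13),
                rect_mask(30, 30, 10, 13, 1, 4), rect_mask(30, 30, 10, 13, 10, 13))
  gt <- scene_from_masks(masks, c(1, 1, 2, 2))
  wrong <- scene_from_masks(masks, c(2, 1, 2, 2))
  map <- gt$instance_map; map[map == 1L] <- 0L
  missed <- annotated_scene(map, gt$class_of[-1])
  agg_wrong <- aggregate_pq(list(gt), list(wrong))
  agg_missed <- aggregate_pq(list(gt), list(missed))
  expect_lt(agg_wrong$apq, agg_missed$apq)
  expect_lt(agg_wrong$mpq, agg_missed$mpq)
  # hand values: wrong: class1 (tp1 fn1) 2/3, class2 (tp2 fp1) 0.8
  expect_equal(agg_wrong$apq, mean(c(2 / 3, 0.8)))
  expect_equal(agg_missed$apq, mean(c(2 / 3, 1)))
})

test_that("ambiguous regions are excluded before matching", {
  g_masks <- list(rect_mask(20, 20, 1, 4, 1, 4), rect_mask(20, 20, 10, 13, 1, 4))
  amb <- matrix(FALSE, 20, 20); amb[1:6, 1:6] <- TRUE
  gt <- scene_from_masks(g_masks, c(1, 1), ambiguous_mask = amb)
  # prediction misses the ambiguous instance entirely; matches the other
  pred <- scene_from_masks(list(rect_mask(20, 20, 10, 13, 1, 4)), 1)
  m <- match_by_iou(gt, pred, 1)
  expect_equal(nrow(m$pairs), 1)
  expect_length(m$unmatched_gt, 0)   # instance 1 dropped with the region
  q <- pq_class_image(m)
  expect_equal(q$pq, 1)
})
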