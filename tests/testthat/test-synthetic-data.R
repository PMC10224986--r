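test_that("scene generation is deterministic and honours the area spec", {
  spec <- population_spec(height = 400L, width = 400L, n_instances = 40L)
  a <- generate_scene(spec, seed = 5)
  b <- generate_scene(spec, seed = 5)
  expect_identical(a$instance_map, b$instance_map)
  expect_identical(a$class_of, b$class_of)

  # a single fixed-area disc class: all areas equal up to discretization
  fixed <- population_spec(classes = "only", frequencies = 1,
                           area_median = 200, area_q1 = 200, area_q3 = 200,
                           shape_family = "disc", height = 300L, width = 300L,
                           n_instances = 30L)
  sc <- generate_scene(fixed, seed = 2)
  areas <- instance_areas(sc)
  expect_lt(max(abs(areas - 200)), 0.1 * 200)

  # instances respect the minimum gap: no two instance pixels of different
  # IDs are 4-adjacent when min_gap >= 1
  m <- sc$instance_map
  h <- nrow(m); w <- ncol(m)
  vert <- m[-1, ] > 0 & m[-h, ] > 0 & m[-1, ] != m[-h, ]
  horiz <- m[, -1] > 0 & m[, -w] > 0 & m[, -1] != m[, -w]
  expect_false(any(vert) || any(horiz))

  # an impossible request fails with the achievable count
  expect_error(generate_scene(population_spec(height = 60L, width = 60L,
                                              n_instances = 50L), seed = 1),
               "achievable|larger than the image")
})

test_that("per-class area medians track the published statistics", {
  spec <- population_spec(height = 900L, width = 900L, n_instances = 200L)
  scs <- generate_dataset(spec, 4, seed = 19)     # ~200 instances per class
  areas <- unlist(lapply(scs, instance_areas))
  cls <- unlist(lapply(scs, function(s) s$class_of[as.character(scene_ids(s))]))
  med <- tapply(areas, cls, median)
  target <- c(266, 546, 683, 1734)
  expect_true(all(abs(med - target) / target < 0.10))
})

test_that("degradation controls are recovered from the degraded scenes", {
  spec <- population_spec(classes = c("a", "b"), frequencies = c(0.5, 0.5),
                          area_median = c(150, 300), area_q1 = c(120, 250),
                          area_q3 = c(180, 360), height = 800L, width = 800L,
                          n_instances = 250L)
  scs <- generate_dataset(spec, 4, seed = 23)     # 1000 instances
  n <- sum(vapply(scs, function(s) length(scene_ids(s)), 1L))
  expect_equal(n, 1000L)

  # dropout rate: detected fraction within the binomial 99% interval
  drop <- lapply(seq_along(scs), function(i)
    degrade(scs[[i]], degradation_spec(dropout_rate = 0.4), seed = 100 + i))
  kept <- sum(vapply(drop, function(d) length(scene_ids(d$scene)), 1L))
  expect_lt(abs(kept / n - 0.6), 2.58 * sqrt(0.4 * 0.6 / n))

  # detection recall via centroid matching tracks 1 - dropout within 3 SE
  recall <- sum(vapply(seq_along(scs), function(i)
    nrow(match_by_centroid(scs[[i]], drop[[i]]$scene)$pairs), 1L)) / n
  expect_lt(abs(recall - 0.6), 3 * sqrt(0.4 * 0.6 / n))

  # misclassification rate: off-diagonal mass of the matched submatrix
  mis <- lapply(seq_along(scs), function(i)
    degrade(scs[[i]], degradation_spec(misclass_rate = 0.2), seed = 200 + i)$scene)
  conf <- Reduce(`+`, lapply(seq_along(scs), function(i)
    confusion_isc(scs[[i]], mis[[i]], match_by_overlap(scs[[i]], mis[[i]]),
                  classes = 1:2)))
  sub <- unclass(conf)[-1, -1]
  off <- 1 - sum(diag(sub)) / sum(sub)
  expect_lt(abs(off - 0.2), 3 * sqrt(0.2 * 0.8 / sum(sub)))

  # total dropout empties the prediction; a null degradation gives PQ = 1
  expect_length(scene_ids(degrade(scs[[1]],
                                  degradation_spec(dropout_rate = 1))$scene), 0)
  null_pred <- degrade(scs[[1]], degradation_spec(), seed = 1)$scene
  expect_identical(null_pred$instance_map, scs[[1]]$instance_map)
  expect_equal(aggregate_pq(list(scs[[1]]), list(null_pred))$apq, 1)
})

test_that("the degradation log records every applied change", {
  set.seed(6)
  gt <- random_boxes_scene(n = 8L)
  d <- degrade(gt, degradation_spec(dropout_rate = 0.3, misclass_rate = 0.3,
                                    spurious_rate = 2), seed = 42)
  log <- d$log
  expect_setequal(log$id[!log$spurious], scene_ids(gt))
  expect_equal(sum(!log$dropped & !log$spurious) + sum(log$spurious),
               length(scene_ids(d$scene)))
  flipped <- !log$spurious & !log$dropped & log$class_from != log$class_to
  for (id in log$id[flipped])
    expect_equal(unname(d$scene$class_of[as.character(id)]),
                 log$class_to[log$id == id & !log$spurious])
})

test_that("simulated raters reproduce jitter and bias structure", {
  spec <- population_spec(classes = c("small", "large"), frequencies = c(0.5, 0.5),
                          area_median = c(120, 900), area_q1 = c(100, 700),
                          area_q3 = c(150, 1100), height = 420L, width = 420L,
                          n_instances = 50L)
  sc <- generate_scene(spec, seed = 31)

  # zero jitter and bias: all raters identical to the source
  same <- simulate_raters(sc, rater_spec(2, jitter_px = 0, bias_px = 0), seed = 1)
  expect_identical(same[[1]]$instance_map, sc$instance_map)
  expect_identical(same[[2]]$instance_map, sc$instance_map)

  # 1 px jitter: small instances disagree more than large ones
  rs <- simulate_raters(sc, rater_spec(2, jitter_px = 1), seed = 7)
  m <- match_by_overlap(rs[[1]], rs[[2]])
  cls <- rs[[1]]$class_of[as.character(m$pairs$gt_id)]
  expect_lt(median(m$pairs$iou[cls == 1]), median(m$pairs$iou[cls == 2]))

  # opposing pure biases: systematic IoU < 1 with small HD
  bias <- simulate_raters(sc, rater_spec(2, jitter_px = 0, bias_px = c(-1, 1)),
                          seed = 9)
  mb <- match_by_overlap(bias[[1]], bias[[2]])
  hd <- nucleval:::pair_hausdorff(bias[[1]], bias[[2]], mb$pairs)
  expect_true(all(mb$pairs$iou < 1))
  expect_lte(max(hd), 3)
})
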