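# fixtures built in code: small masks, scenes, and independent brute-force
# oracles used to cross-check the implementation

mask_from_coords <- function(h, w, pts) {
  m <- matrix(FALSE, h, w)
  if (length(pts)) m[matrix(pts, ncol = 2, byrow = TRUE)] <- TRUE
  m
}

rect_mask <- function(h, w, r1, r2, c1, c2) {
  m <- matrix(FALSE, h, w)
  m[r1:r2, c1:c2] <- TRUE
  m
}

random_mask <- function(h, w, n_px) {
  idx <- sample.int(h * w, n_px)
  m <- matrix(FALSE, h, w)
  m[idx] <- TRUE
  m
}

# a connected random blob grown from a seed pixel
random_blob <- function(h, w, n_px, border = 2L) {
  m <- matrix(FALSE, h, w)
  r <- sample((1L + border):(h - border), 1L)
  c <- sample((1L + border):(w - border), 1L)
  m[r, c] <- TRUE
  while (sum(m) < n_px) {
    cand <- which((!m) & nucleval::dilate1(m))
    pts <- arrayInd(cand, dim(m))
    ok <- pts[, 1] > border & pts[, 1] <= h - border &
      pts[, 2] > border & pts[, 2] <= w - border
    if (!any(ok)) break
    pick <- cand[ok][sample.int(sum(ok), 1L)]
    m[pick] <- TRUE
  }
  m
}

# scene from a list of non-overlapping masks; IDs are 1..n in list order
scene_from_masks <- function(masks, classes, ...) {
  map <- matrix(0L, nrow(masks[[1]]), ncol(masks[[1]]))
  for (i in seq_along(masks)) {
    stopifnot(!any(map[masks[[i]]] != 0L))
    map[masks[[i]]] <- i
  }
  annotated_scene(map, stats::setNames(classes, seq_along(masks)), ...)
}

# random scene of non-overlapping axis-aligned boxes
random_boxes_scene <- function(h = 48L, w = 48L, n = 6L, n_classes = 2L) {
  masks <- list()
  occ <- matrix(FALSE, h, w)
  while (length(masks) < n) {
    bh <- sample(3:7, 1L); bw <- sample(3:7, 1L)
    r1 <- sample.int(h - bh, 1L); c1 <- sample.int(w - bw, 1L)
    m <- rect_mask(h, w, r1, r1 + bh - 1L, c1, c1 + bw - 1L)
    if (!any(occ & m)) {
      occ <- occ | m
      masks[[length(masks) + 1L]] <- m
    }
  }
  scene_from_masks(masks, sample.int(n_classes, n, replace = TRUE))
}

# ---- brute-force oracles --------------------------------------------------

bf_overlap <- function(g, p) {
  tp <- 0L; fp <- 0L; fn <- 0L
  for (r in seq_len(nrow(g))) for (c in seq_len(ncol(g))) {
    if (g[r, c] && p[r, c]) tp <- tp + 1L
    else if (p[r, c]) fp <- fp + 1L
    else if (g[r, c]) fn <- fn + 1L
  }
  list(tp = tp, fp = fp, fn = fn)
}

bf_iou <- function(g, p) {
  ov <- bf_overlap(g, p)
  ov$tp / (ov$tp + ov$fp + ov$fn)
}

bf_contour_points <- function(m) {
  pts <- NULL
  h <- nrow(m); w <- ncol(m)
  for (r in seq_len(h)) for (c in seq_len(w)) {
    if (!m[r, c]) next
    nb_out <- (r == 1 || !m[r - 1, c]) || (r == h || !m[r + 1, c]) ||
      (c == 1 || !m[r, c - 1]) || (c == w || !m[r, c + 1])
    if (nb_out) pts <- rbind(pts, c(r, c))
  }
  pts
}

bf_hausdorff <- function(a, b) {
  pa <- bf_contour_points(a); pb <- bf_contour_points(b)
  directed <- function(x, y) {
    worst <- 0
    for (i in seq_len(nrow(x))) {
      best <- Inf
      for (j in seq_len(nrow(y)))
        best <- min(best, sqrt(sum((x[i, ] - y[j, ])^2)))
      worst <- max(worst, best)
    }
    worst
  }
  max(directed(pa, pb), directed(pb, pa))
}

# all-pairs strict-IoU matcher over every class, for uniqueness checks
bf_match_pairs <- function(gt, pred, threshold = 0.5) {
  out <- NULL
  for (g in scene_ids(gt)) for (p in scene_ids(pred)) {
    if (gt$class_of[as.character(g)] != pred$class_of[as.character(p)]) next
    v <- tryCatch(iou(instance_mask(gt, g), instance_mask(pred, p)),
                  error = function(e) 0)
    if (v > threshold) out <- rbind(out, data.frame(gt_id = g, pred_id = p, iou = v))
  }
  out
}

# standard two-class population at published per-class area statistics
two_class_spec <- function(height, width, n_instances) {
  population_spec(classes = c("lymphocyte", "epithelial"),
                  frequencies = c(0.5, 0.5),
                  area_median = c(266, 683), area_q1 = c(221, 524),
                  area_q3 = c(314, 858),
                  height = height, width = width, n_instances = n_instances)
}
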