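#' @importFrom stats median quantile qnorm rlnorm rpois runif rnorm lm coef setNames
#' @importFrom utils write.csv
#' @importFrom data.table data.table setnames setorderv :=
NULL

# ---- instance masks -------------------------------------------------------
#
# An instance mask is a logical matrix on the image grid (TRUE = instance
# pixel).  All geometry below is pixel-set geometry: coordinates are (row,
# col) with origin top-left, and distances are Euclidean distances between
# pixel centers.

check_mask <- function(m, arg = "mask") {
  if (!is.matrix(m) || !is.logical(m))
    stop(sprintf("`%s` must be a logical matrix", arg), call. = FALSE)
  invisible(m)
}

check_same_dim <- function(a, b) {
  if (!all(dim(a) == dim(b)))
    stop(sprintf("mask dimensions differ: %dx%d vs %dx%d",
                 nrow(a), ncol(a), nrow(b), ncol(b)), call. = FALSE)
  invisible(NULL)
}

#' Translate a logical mask on its grid
#'
#' Pixels shifted past the image border are lost; vacated pixels are FALSE.
#'
#' @param m logical matrix.
#' @param dr,dc integer shift in rows (down is positive) and columns.
#' @return logical matrix of the same dimensions.
#' @keywords internal
shift_mask <- function(m, dr, dc) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(FALSE, h, w)
  r_dst <- seq_len(h); c_dst <- seq_len(w)
  keep_r <- r_dst - dr >= 1L & r_dst - dr <= h
  keep_c <- c_dst - dc >= 1L & c_dst - dc <= w
  if (any(keep_r) && any(keep_c))
    out[r_dst[keep_r], c_dst[keep_c]] <- m[r_dst[keep_r] - dr, c_dst[keep_c] - dc]
  out
}

# sample one element of x (safe for length-1 vectors, unlike sample())
resample1 <- function(x) x[sample.int(length(x), 1L)]

kernel_shifts <- function(kernel = c("cross", "square")) {
  kernel <- match.arg(kernel)
  s <- list(c(1L, 0L), c(-1L, 0L), c(0L, 1L), c(0L, -1L))
  if (kernel == "square")
    s <- c(s, list(c(1L, 1L), c(1L, -1L), c(-1L, 1L), c(-1L, -1L)))
  s
}

erode_mask <- function(m, kernel = "cross") {
  out <- m
  for (s in kernel_shifts(kernel)) out <- out & shift_mask(m, s[1], s[2])
  out
}

dilate_mask <- function(m, kernel = "cross") {
  out <- m
  for (s in kernel_shifts(kernel)) out <- out | shift_mask(m, s[1], s[2])
  out
}

#' Per-pixel overlap counts between two instance masks
#'
#' Counts true-positive, false-positive and false-negative pixels of a
#' predicted mask `p` against a ground-truth mask `g`:
#' TP = |g intersect p|, FP = |p \\ g|, FN = |g \\ p|.
#'
#' @param g,p logical matrices of identical dimensions.
#' @return list with integer fields `tp`, `fp`, `fn`.
#' @examples
#' g <- matrix(FALSE, 4, 4); g[1:2, 1:2] <- TRUE
#' p <- matrix(FALSE, 4, 4); p[2:3, 1:2] <- TRUE
#' pixel_overlap(g, p)
#' @export
pixel_overlap <- function(g, p) {
  check_mask(g, "g"); check_mask(p, "p"); check_same_dim(g, p)
  tp <- sum(g & p)
  list(tp = tp, fp = sum(p) - tp, fn = sum(g) - tp)
}

#' Intersection over Union of two masks
#'
#' IoU(g, p) = |g intersect p| / |g union p|, equivalently
#' TP / (TP + FP + FN) on pixel counts.  Two empty masks have no defined
#' IoU and raise an error: callers must filter empty instances first.
#'
#' @inheritParams pixel_overlap
#' @return a fraction in \[0, 1\].
#' @export
iou <- function(g, p) {
  ov <- pixel_overlap(g, p)
  u <- ov$tp + ov$fp + ov$fn
  if (u == 0) stop("IoU of two empty masks is undefined", call. = FALSE)
  ov$tp / u
}

#' Analytic IoU after pure overestimation
#'
#' If a perfectly matching prediction gains `n` background pixels, the IoU
#' drops to TP / (TP + n): the added pixels only enlarge the union.
#'
#' @param tp true-positive pixel count (> 0), i.e. the object area.
#' @param n number of overestimated pixels (>= 0).
#' @return a fraction in (0, 1\].
#' @export
iou_over <- function(tp, n) {
  if (tp <= 0) stop("`tp` must be positive", call. = FALSE)
  if (n < 0) stop("`n` must be non-negative", call. = FALSE)
  tp / (tp + n)
}

#' Analytic IoU after pure underestimation
#'
#' If `n` pixels are removed from the true-positive set, each removed pixel
#' counts both as a lost true positive and as a new false negative, giving
#' (TP - n) / (TP + n) — a steeper penalty than overestimation by the same
#' `n` pixels.
#'
#' @inheritParams iou_over
#' @param n number of underestimated pixels, 0 <= n < tp.
#' @return a fraction in (0, 1\].
#' @export
iou_under <- function(tp, n) {
  if (tp <= 0) stop("`tp` must be positive", call. = FALSE)
  if (n < 0 || n >= tp) stop("`n` must satisfy 0 <= n < tp", call. = FALSE)
  (tp - n) / (tp + n)
}

#' Contour of an instance mask
#'
#' The contour is the set of instance pixels with at least one 4-neighbour
#' outside the instance; pixels on the image edge count their out-of-image
#' neighbours as outside.
#'
#' @param m non-empty logical matrix.
#' @return logical matrix marking the boundary pixels (a subset of `m`).
#' @export
contour_mask <- function(m) {
  check_mask(m)
  if (!any(m)) stop("contour of an empty mask is undefined", call. = FALSE)
  m & !erode_mask(m, "cross")
}

mask_points <- function(m) which(m, arr.ind = TRUE)

# argmin per row of a squared-distance matrix, without apply()
row_min <- function(d2) d2[cbind(seq_len(nrow(d2)), max.col(-d2))]

#' Hausdorff distance between two instance masks
#'
#' The symmetric Hausdorff distance between the two contours: the larger of
#' the two directed distances max over one contour of the Euclidean distance
#' to the closest point of the other contour.  Computed on pixel contours
#' (4-connectivity boundary) between pixel centers.
#'
#' @param a,b non-empty logical matrices of identical dimensions.
#' @return distance in pixels; 0 iff the contours are identical.
#' @export
hausdorff <- function(a, b) {
  check_mask(a, "a"); check_mask(b, "b"); check_same_dim(a, b)
  pa <- mask_points(contour_mask(a))
  pb <- mask_points(contour_mask(b))
  d2 <- outer(pa[, 1], pb[, 1], `-`)^2 + outer(pa[, 2], pb[, 2], `-`)^2
  sqrt(max(max(row_min(d2)), max(row_min(t(d2)))))
}

# Hausdorff distances for matched instance pairs of two scenes, computed on
# per-pair crops (translation-invariant, so cropping is exact).
pair_hausdorff <- function(gt, pred, pairs) {
  if (!nrow(pairs)) return(numeric(0))
  h <- gt$height; w <- gt$width
  pg <- instance_index_list(gt$instance_map)
  pp <- instance_index_list(pred$instance_map)
  vapply(seq_len(nrow(pairs)), function(k) {
    ia <- pg[[as.character(pairs$gt_id[k])]]
    ib <- pp[[as.character(pairs$pred_id[k])]]
    cr <- crop_instance(c(ia, ib), h, w, margin = 1L)
    ra <- ((ia - 1L) %% h) + 1L - cr$r0; ca <- ((ia - 1L) %/% h) + 1L - cr$c0
    rb <- ((ib - 1L) %% h) + 1L - cr$r0; cb <- ((ib - 1L) %/% h) + 1L - cr$c0
    ma <- matrix(FALSE, nrow(cr$mask), ncol(cr$mask))
    mb <- ma
    ma[cbind(ra, ca)] <- TRUE
    mb[cbind(rb, cb)] <- TRUE
    hausdorff(ma, mb)
  }, numeric(1))
}

#' Centroid of an instance mask
#'
#' @param m non-empty logical matrix.
#' @return numeric `(row, col)` — the arithmetic mean of the pixel coordinates.
#' @export
centroid <- function(m) {
  check_mask(m)
  if (!any(m)) stop("centroid of an empty mask is undefined", call. = FALSE)
  pts <- mask_points(m)
  c(row = mean(pts[, 1]), col = mean(pts[, 2]))
}
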