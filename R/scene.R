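# ---- annotated scenes -----------------------------------------------------

#' Construct an annotated scene
#'
#' A scene holds one image's instances: a single-valued instance-ID map
#' (0 = background, positive integers = instance IDs, not necessarily
#' contiguous), a class label in `1..m` for every instance, and an optional
#' binary mask of ambiguous regions that are excluded from evaluation.
#' Because the ID map is single-valued, instances cannot overlap.
#'
#' @param instance_map integer matrix; 0 is background.
#' @param class_of named integer vector mapping instance ID (as name) to a
#'   class label >= 1.  Must cover every nonzero ID in `instance_map`.
#' @param ambiguous_mask optional logical matrix of the same dimensions.
#' @param class_names optional character vector naming the class labels.
#' @return an object of class `annotated_scene`.
#' @export
annotated_scene <- function(instance_map, class_of, ambiguous_mask = NULL,
                            class_names = NULL) {
  if (!is.matrix(instance_map))
    stop("`instance_map` must be a matrix", call. = FALSE)
  storage.mode(instance_map) <- "integer"
  if (any(instance_map < 0L, na.rm = TRUE))
    stop("instance IDs must be non-negative", call. = FALSE)
  ids <- sort(unique(instance_map[instance_map > 0L]))
  class_of <- as.integer(class_of[as.character(ids)])
  if (length(ids) && anyNA(class_of))
    stop("every instance ID in the map needs a class label", call. = FALSE)
  names(class_of) <- as.character(ids)
  if (!is.null(ambiguous_mask)) {
    check_mask(ambiguous_mask, "ambiguous_mask")
    check_same_dim(instance_map, ambiguous_mask)
  }
  structure(
    list(instance_map = instance_map, class_of = class_of,
         ambiguous_mask = ambiguous_mask, class_names = class_names,
         height = nrow(instance_map), width = ncol(instance_map)),
    class = "annotated_scene")
}

#' @export
print.annotated_scene <- function(x, ...) {
  cat(sprintf("<annotated_scene> %d x %d px, %d instances, %d classes%s\n",
              x$height, x$width, length(x$class_of),
              length(unique(x$class_of)),
              if (is.null(x$ambiguous_mask)) "" else ", ambiguous mask"))
  invisible(x)
}

#' Instance IDs of a scene
#' @param scene an `annotated_scene`.
#' @return integer vector of IDs (sorted).
#' @export
scene_ids <- function(scene) as.integer(names(scene$class_of))

#' Class labels present in a scene
#' @param scene an `annotated_scene`.
#' @return sorted integer vector of distinct class labels.
#' @export
scene_classes <- function(scene) sort(unique(unname(scene$class_of)))

#' Per-instance pixel areas
#' @param scene an `annotated_scene`.
#' @return named integer vector (names = instance IDs).
#' @export
instance_areas <- function(scene) {
  m <- scene$instance_map
  v <- m[m > 0L]
  if (!length(v)) return(setNames(integer(0), character(0)))
  tab <- table(v)
  setNames(as.integer(tab), names(tab))
}

# linear (column-major) indices of every instance's pixels, as a named list
instance_index_list <- function(map) {
  idx <- which(map != 0L)
  if (!length(idx)) return(list())
  split(idx, map[idx])
}

# crop one instance (given by linear indices) to a logical matrix with a
# margin, clipped to the image; returns the mask plus its offset so that
# crop pixel (r, c) sits at image pixel (r + r0, c + c0)
crop_instance <- function(idx, h, w, margin = 1L) {
  r <- ((idx - 1L) %% h) + 1L
  c <- ((idx - 1L) %/% h) + 1L
  r1 <- max(1L, min(r) - margin); r2 <- min(h, max(r) + margin)
  c1 <- max(1L, min(c) - margin); c2 <- min(w, max(c) + margin)
  m <- matrix(FALSE, r2 - r1 + 1L, c2 - c1 + 1L)
  m[cbind(r - r1 + 1L, c - c1 + 1L)] <- TRUE
  list(mask = m, r0 = r1 - 1L, c0 = c1 - 1L)
}

#' Extract one instance as a full-size logical mask
#' @param scene an `annotated_scene`.
#' @param id instance ID.
#' @return logical matrix of the scene's dimensions.
#' @export
instance_mask <- function(scene, id) {
  m <- scene$instance_map == id
  if (!any(m)) stop(sprintf("no instance with ID %s", id), call. = FALSE)
  m
}

#' Per-instance centroids
#' @param scene an `annotated_scene`.
#' @return matrix with columns `row`, `col` and rownames = instance IDs.
#' @export
scene_centroids <- function(scene) {
  h <- scene$height
  lst <- instance_index_list(scene$instance_map)
  out <- t(vapply(lst, function(idx) {
    c(mean(((idx - 1L) %% h) + 1L), mean(((idx - 1L) %/% h) + 1L))
  }, numeric(2)))
  colnames(out) <- c("row", "col")
  out
}

# Remove ambiguous-region pixels from a scene; instances emptied by the
# removal are dropped entirely.
apply_ambiguous <- function(scene, mask) {
  if (is.null(mask)) return(scene)
  map <- scene$instance_map
  map[mask] <- 0L
  keep <- unique(map[map > 0L])
  annotated_scene(map, scene$class_of[as.character(keep)],
                  class_names = scene$class_names)
}

# Shared ambiguous mask of a gt/pred pair (union), applied to both scenes
# before any overlap computation.
mask_ambiguous_pair <- function(gt, pred) {
  amb <- gt$ambiguous_mask
  if (!is.null(pred$ambiguous_mask))
    amb <- if (is.null(amb)) pred$ambiguous_mask else (amb | pred$ambiguous_mask)
  list(gt = apply_ambiguous(gt, amb), pred = apply_ambiguous(pred, amb))
}

# All overlapping (gt, pred) instance pairs with intersection and IoU.
# Returns a data.table with columns g, p, inter, area_g, area_p, iou.
pair_overlaps <- function(gt, pred) {
  gm <- gt$instance_map; pm <- pred$instance_map
  check_same_dim(gm, pm)
  sel <- gm != 0L | pm != 0L
  g <- gm[sel]; p <- pm[sel]
  dt <- data.table::data.table(g = g, p = p)
  counts <- dt[, .N, by = c("g", "p")]
  ag <- counts[counts$g > 0L, list(area_g = sum(N)), by = "g"]
  ap <- counts[counts$p > 0L, list(area_p = sum(N)), by = "p"]
  pairs <- counts[counts$g > 0L & counts$p > 0L]
  data.table::setnames(pairs, "N", "inter")
  pairs <- merge(pairs, ag, by = "g")
  pairs <- merge(pairs, ap, by = "p")
  pairs$iou <- pairs$inter / (pairs$area_g + pairs$area_p - pairs$inter)
  data.table::setorderv(pairs, c("g", "p"))
  pairs[, c("g", "p", "inter", "area_g", "area_p", "iou")]
}
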