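# ---- mask and scene perturbations -----------------------------------------
#
# Single-pixel morphological perturbations used to probe IoU sensitivity.
# The structuring element is a 3x3 cross (4-connectivity) by default — the
# minimal isotropic choice — switchable to the 3x3 square.

#' Single-pixel erosion of an instance mask
#'
#' Binary erosion with a 3x3 structuring element applied to the instance
#' alone on its image grid; pixels outside the image count as background,
#' so instances touching the border erode there too.  The result may be
#' empty (a one-pixel instance disappears).
#'
#' @param m non-empty logical matrix.
#' @param kernel `"cross"` (4-connectivity, default) or `"square"`.
#' @return logical matrix; possibly all-FALSE.
#' @export
erode1 <- function(m, kernel = c("cross", "square")) {
  check_mask(m)
  if (!any(m)) stop("cannot erode an empty mask", call. = FALSE)
  erode_mask(m, match.arg(kernel))
}

#' Single-pixel dilation of an instance mask
#'
#' Binary dilation with a 3x3 structuring element, clipped to the image
#' bounds.  Dilation is computed against the instance alone: neighbouring
#' instances are ignored.
#'
#' @inheritParams erode1
#' @return logical matrix containing the input mask.
#' @export
dilate1 <- function(m, kernel = c("cross", "square")) {
  check_mask(m)
  if (!any(m)) stop("cannot dilate an empty mask", call. = FALSE)
  dilate_mask(m, match.arg(kernel))
}

#' Single-pixel vertical shift of a whole scene
#'
#' Translates the instance map one row downward; pixels shifted past the
#' bottom border are lost.  Class labels are preserved (instances shifted
#' entirely out of the image are dropped).
#'
#' @param scene an `annotated_scene`.
#' @return an `annotated_scene`.
#' @export
shift1 <- function(scene) {
  map <- scene$instance_map
  h <- nrow(map)
  out <- rbind(matrix(0L, 1L, ncol(map)), map[-h, , drop = FALSE])
  keep <- unique(out[out > 0L])
  annotated_scene(out, scene$class_of[as.character(keep)],
                  ambiguous_mask = scene$ambiguous_mask,
                  class_names = scene$class_names)
}

#' Downscale a scene by a factor of two
#'
#' Nearest-neighbour subsampling at the odd (1-based) rows and columns,
#' emulating evaluation at half the magnification.  Instances whose every
#' pixel falls between sample points disappear and are dropped with a
#' warning.
#'
#' @param scene an `annotated_scene`.
#' @return an `annotated_scene` of half the dimensions (rounded up).
#' @export
downscale2 <- function(scene) {
  map <- scene$instance_map[seq(1L, scene$height, by = 2L),
                            seq(1L, scene$width, by = 2L), drop = FALSE]
  amb <- scene$ambiguous_mask
  if (!is.null(amb))
    amb <- amb[seq(1L, scene$height, by = 2L), seq(1L, scene$width, by = 2L),
               drop = FALSE]
  keep <- unique(map[map > 0L])
  lost <- setdiff(scene_ids(scene), keep)
  if (length(lost))
    warning(sprintf("%d instance(s) emptied by downscaling were dropped",
                    length(lost)))
  annotated_scene(map, scene$class_of[as.character(keep)],
                  ambiguous_mask = amb, class_names = scene$class_names)
}

#' Analytic IoU of an ideal disc and its single-pixel erosion
#'
#' In the continuous limit a disc of radius r eroded by one pixel keeps
#' area pi (r-1)^2 out of pi r^2, giving IoU = (r-1)^2 / r^2.  Serves as a
#' tolerance oracle for rasterized discs.
#'
#' @param radius disc radius in pixels (>= 2).
#' @return a fraction in (0, 1).
#' @export
disc_erosion_iou <- function(radius) {
  if (any(radius < 2)) stop("`radius` must be at least 2", call. = FALSE)
  (radius - 1)^2 / radius^2
}

#' Rasterize an ideal disc
#'
#' @param radius disc radius in pixels.
#' @return logical matrix of side `2 * ceiling(radius) + 3` with the disc
#'   centered (one-pixel free border for morphology).
#' @export
raster_disc <- function(radius) {
  n <- 2L * as.integer(ceiling(radius)) + 3L
  ctr <- (n + 1) / 2
  r <- matrix(seq_len(n), n, n)
  c <- t(r)
  (r - ctr)^2 + (c - ctr)^2 <= radius^2
}

# instance-local IoU of a mask against a unary perturbation of itself
perturb_one <- function(mask, kind, kernel) {
  out <- switch(kind,
    erode1 = erode_mask(mask, kernel),
    dilate1 = dilate_mask(mask, kernel),
    none = mask,
    stop(sprintf("unknown per-instance perturbation '%s'", kind), call. = FALSE))
  inter <- sum(mask & out)
  union <- sum(mask | out)
  list(iou = if (union == 0) 0 else inter / union, emptied = !any(out))
}

# IoU of each instance against its one-row-down shifted self, directly from
# linear pixel indices (column-major: +1 moves one row down within a column)
shift_iou <- function(idx, h) {
  r <- ((idx - 1L) %% h) + 1L
  shifted <- idx[r < h] + 1L
  inter <- sum(shifted %in% idx)
  inter / (2L * length(idx) - inter)
}

#' Sweep single-pixel perturbations over scene populations
#'
#' Applies each requested perturbation to every instance and records the
#' IoU of the perturbed instance against the original, together with the
#' instance's class and pixel area.  The `down2_*` kinds first downscale
#' the scene by two, then perturb on the coarser grid; their areas are the
#' post-downscale areas.  Instance-local perturbations (erosion, dilation)
#' are evaluated per instance in isolation.
#'
#' @param scenes an `annotated_scene` or list thereof.
#' @param kinds subset of `c("erode1", "dilate1", "shift1", "down2_erode1",
#'   "down2_dilate1", "none")`.
#' @param kernel structuring element, `"cross"` or `"square"`; recorded in
#'   the result's `"kernel"` attribute.
#' @return data.frame with columns scene, instance_id, class_label,
#'   area_px, perturbation, iou_after, emptied.
#' @export
perturbation_sweep <- function(scenes,
                               kinds = c("erode1", "dilate1", "shift1"),
                               kernel = c("cross", "square")) {
  kernel <- match.arg(kernel)
  if (inherits(scenes, "annotated_scene")) scenes <- list(scenes)
  if (!length(scenes)) stop("empty scene list", call. = FALSE)
  known <- c("erode1", "dilate1", "shift1", "down2_erode1", "down2_dilate1", "none")
  if (!all(kinds %in% known))
    stop("unknown perturbation kind(s): ",
         paste(setdiff(kinds, known), collapse = ", "), call. = FALSE)
  rows <- list()
  emit <- function(scene_i, id, cl, area, kind, iou_v, emptied) {
    rows[[length(rows) + 1L]] <<-
      data.frame(scene = scene_i, instance_id = id, class_label = cl,
                 area_px = area, perturbation = kind, iou_after = iou_v,
                 emptied = emptied)
  }
  sweep_scene <- function(scene, scene_i, kind_set, prefix = "") {
    h <- scene$height; w <- scene$width
    px <- instance_index_list(scene$instance_map)
    for (id_chr in names(px)) {
      idx <- px[[id_chr]]
      id <- as.integer(id_chr)
      cl <- unname(scene$class_of[id_chr])
      area <- length(idx)
      for (kind in kind_set) {
        if (kind == "shift1") {
          v <- shift_iou(idx, h)
          emit(scene_i, id, cl, area, paste0(prefix, kind), v, v == 0)
        } else {
          cr <- crop_instance(idx, h, w, margin = 1L)
          pv <- perturb_one(cr$mask, kind, kernel)
          emit(scene_i, id, cl, area, paste0(prefix, kind), pv$iou, pv$emptied)
        }
      }
    }
  }
  base_kinds <- intersect(kinds, c("erode1", "dilate1", "shift1", "none"))
  down_kinds <- sub("^down2_", "", intersect(kinds, c("down2_erode1", "down2_dilate1")))
  for (i in seq_along(scenes)) {
    if (length(base_kinds)) sweep_scene(scenes[[i]], i, base_kinds)
    if (length(down_kinds)) {
      ds <- withCallingHandlers(downscale2(scenes[[i]]),
                                warning = function(w) invokeRestart("muffleWarning"))
      sweep_scene(ds, i, down_kinds, prefix = "down2_")
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(scene = integer(0), instance_id = integer(0),
               class_label = integer(0), area_px = integer(0),
               perturbation = character(0), iou_after = numeric(0),
               emptied = logical(0))
  attr(out, "kernel") <- kernel
  out
}
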