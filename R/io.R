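# ---- scene I/O ------------------------------------------------------------
#
# Native on-disk format: paired single-channel 16-bit TIFF label maps
# (instance-ID map + class map, 0 = background) with an optional JSON
# sidecar naming the classes.

read_label_tiff <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  img <- tiff::readTIFF(path, as.is = FALSE)
  if (length(dim(img)) == 3L) {
    if (dim(img)[3] != 1L)
      stop(sprintf("%s: label maps must be single-channel", path), call. = FALSE)
    img <- img[, , 1]
  }
  v <- img * 65535
  if (max(abs(v - round(v))) > 1e-6)
    stop(sprintf("%s: non-integer pixel values", path), call. = FALSE)
  m <- round(v)
  storage.mode(m) <- "integer"
  m
}

#' Read an annotated scene from paired label maps
#'
#' The class of each instance is the majority class-map value over its
#' pixels; instances whose class map is mixed are resolved by majority
#' vote and reported via a message (or an error in strict mode).  An
#' instance with no nonzero class pixel is a format error.
#'
#' @param instance_path path to the 16-bit instance-ID TIFF.
#' @param class_path path to the matching class-label TIFF.
#' @param ambiguous_path optional path to a binary exclusion-mask TIFF.
#' @param strict error (rather than vote) on instance/class disagreement.
#' @return an `annotated_scene`.
#' @export
read_scene <- function(instance_path, class_path, ambiguous_path = NULL,
                       strict = FALSE) {
  imap <- read_label_tiff(instance_path)
  cmap <- read_label_tiff(class_path)
  if (!all(dim(imap) == dim(cmap)))
    stop(sprintf("dimension mismatch between %s and %s",
                 instance_path, class_path), call. = FALSE)
  amb <- NULL
  if (!is.null(ambiguous_path)) {
    amb <- read_label_tiff(ambiguous_path)
    if (!all(dim(amb) == dim(imap)))
      stop(sprintf("dimension mismatch between %s and %s",
                   instance_path, ambiguous_path), call. = FALSE)
    amb <- amb != 0L
  }
  px <- instance_index_list(imap)
  class_of <- vapply(names(px), function(id_chr) {
    cls <- cmap[px[[id_chr]]]
    cls <- cls[cls != 0L]
    if (!length(cls))
      stop(sprintf("%s: instance %s has no class pixels in %s",
                   instance_path, id_chr, class_path), call. = FALSE)
    tab <- table(cls)
    if (length(tab) > 1L) {
      if (strict)
        stop(sprintf("%s: instance %s has mixed class labels", class_path, id_chr),
             call. = FALSE)
      message(sprintf("instance %s has mixed class labels; majority vote applied",
                      id_chr))
    }
    as.integer(names(tab)[which.max(tab)])
  }, integer(1))
  annotated_scene(imap, class_of, ambiguous_mask = amb)
}

#' Write an annotated scene as paired label maps
#'
#' @param scene an `annotated_scene`.
#' @param instance_path,class_path output TIFF paths.
#' @param ambiguous_path optional output path for the exclusion mask.
#' @param sidecar_path optional JSON path recording class names.
#' @return invisibly, the paths written.
#' @export
write_scene <- function(scene, instance_path, class_path,
                        ambiguous_path = NULL, sidecar_path = NULL) {
  if (max(c(0L, scene$instance_map)) > 65535L)
    stop("instance IDs above 65535 cannot be stored in 16-bit maps", call. = FALSE)
  cmap <- matrix(0L, scene$height, scene$width)
  for (id_chr in names(scene$class_of))
    cmap[scene$instance_map == as.integer(id_chr)] <- scene$class_of[id_chr]
  tiff::writeTIFF(scene$instance_map / 65535, instance_path,
                  bits.per.sample = 16L, compression = "none")
  tiff::writeTIFF(cmap / 65535, class_path,
                  bits.per.sample = 16L, compression = "none")
  paths <- c(instance_path, class_path)
  if (!is.null(ambiguous_path)) {
    amb <- if (is.null(scene$ambiguous_mask))
      matrix(0L, scene$height, scene$width) else scene$ambiguous_mask * 1L
    tiff::writeTIFF(amb / 65535, ambiguous_path,
                    bits.per.sample = 16L, compression = "none")
    paths <- c(paths, ambiguous_path)
  }
  if (!is.null(sidecar_path)) {
    jsonlite::write_json(list(class_names = scene$class_names,
                              height = scene$height, width = scene$width),
                         sidecar_path, auto_unbox = TRUE, null = "null")
    paths <- c(paths, sidecar_path)
  }
  invisible(paths)
}

#' Read a challenge-style per-instance binary-mask directory
#'
#' Adapter for datasets that ship one binary mask image per instance,
#' grouped in one subdirectory per class:
#' `dir/<class name>/<instance>.tif`.  Masks are combined into a single
#' scene; where masks overlap, the first-read instance keeps the pixel
#' (reported via a message).
#'
#' @param dir directory containing one subdirectory per class.
#' @param class_names optional character vector fixing the class order;
#'   defaults to the sorted subdirectory names.
#' @return an `annotated_scene`.
#' @export
read_mask_dir <- function(dir, class_names = NULL) {
  if (!dir.exists(dir)) stop(sprintf("no such directory: %s", dir), call. = FALSE)
  subdirs <- list.dirs(dir, recursive = FALSE)
  if (!length(subdirs)) stop(sprintf("%s: no class subdirectories", dir), call. = FALSE)
  if (is.null(class_names)) class_names <- sort(basename(subdirs))
  map <- NULL
  class_of <- integer(0)
  next_id <- 1L
  n_clipped <- 0L
  for (cl in seq_along(class_names)) {
    sd <- file.path(dir, class_names[cl])
    if (!dir.exists(sd)) next
    for (f in sort(list.files(sd, pattern = "\\.tiff?$", full.names = TRUE))) {
      m <- read_label_tiff(f)
      if (is.null(map)) map <- matrix(0L, nrow(m), ncol(m))
      if (!all(dim(m) == dim(map)))
        stop(sprintf("%s: dimension mismatch within mask directory", f), call. = FALSE)
      idx <- which(m != 0L)
      clipped <- sum(map[idx] != 0L)
      if (clipped > 0L) n_clipped <- n_clipped + 1L
      idx <- idx[map[idx] == 0L]
      if (length(idx)) {
        map[idx] <- next_id
        class_of[as.character(next_id)] <- cl
        next_id <- next_id + 1L
      }
    }
  }
  if (n_clipped > 0L)
    message(sprintf("%d overlapping mask(s) clipped to the first-read instance",
                    n_clipped))
  annotated_scene(map, class_of, class_names = class_names)
}

# even-odd scanline test: is each grid point inside the polygon?
point_in_polygon <- function(pr, pc, poly_r, poly_c) {
  n <- length(poly_r)
  inside <- rep(FALSE, length(pr))
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((poly_r[i] > pr) != (poly_r[j] > pr)) &
      (pc < (poly_c[j] - poly_c[i]) * (pr - poly_r[i]) /
         (poly_r[j] - poly_r[i]) + poly_c[i])
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' Read polygon-annotation CSV exports
#'
#' Adapter for datasets that ship nuclei as polygons in a CSV with one row
#' per instance: a class column plus comma-separated vertex coordinate
#' strings.  Polygons are rasterized by an even-odd point-in-polygon test
#' over each polygon's bounding box.
#'
#' @param path CSV file path.
#' @param height,width dimensions of the target label map, px.
#' @param class_col,x_col,y_col column names for the class label and the
#'   comma-separated x (column) and y (row) vertex lists.
#' @return an `annotated_scene`; class labels follow the sorted distinct
#'   class names.
#' @export
read_polygon_csv <- function(path, height, width,
                             class_col = "raw_classification",
                             x_col = "coords_x", y_col = "coords_y") {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (col in c(class_col, x_col, y_col))
    if (!col %in% names(d))
      stop(sprintf("%s: missing column '%s'", path, col), call. = FALSE)
  class_names <- sort(unique(d[[class_col]]))
  map <- matrix(0L, height, width)
  class_of <- integer(0)
  for (i in seq_len(nrow(d))) {
    xs <- as.numeric(strsplit(d[[x_col]][i], ",")[[1]])
    ys <- as.numeric(strsplit(d[[y_col]][i], ",")[[1]])
    if (anyNA(xs) || anyNA(ys) || length(xs) != length(ys) || length(xs) < 3)
      stop(sprintf("%s: malformed polygon in row %d", path, i), call. = FALSE)
    pr <- ys + 1; pc <- xs + 1  # 0-based export to 1-based grid
    rs <- max(1L, floor(min(pr))):min(height, ceiling(max(pr)))
    cs <- max(1L, floor(min(pc))):min(width, ceiling(max(pc)))
    grid <- expand.grid(r = rs, c = cs)
    inside <- point_in_polygon(grid$r, grid$c, pr, pc)
    idx <- grid$r[inside] + (grid$c[inside] - 1L) * height
    idx <- idx[map[idx] == 0L]
    if (length(idx)) {
      map[idx] <- i
      class_of[as.character(i)] <- match(d[[class_col]][i], class_names)
    }
  }
  annotated_scene(map, class_of, class_names = class_names)
}
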