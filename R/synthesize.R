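# ---- synthetic nuclei scenes ----------------------------------------------
#
# Scenes emulate the statistical structure the evaluation experiments rely
# on: multi-class populations with class-specific right-skewed area
# distributions, non-overlapping near-convex instances, and predictions
# degraded by detection dropout, boundary erosion/dilation/jitter,
# misclassification and spurious detections.

#' Specify a synthetic nuclei population
#'
#' Defaults correspond to the four nucleus classes of a 0.25 um/px (40x)
#' H&E test set: lymphocytes are the smallest (median area 266 px,
#' IQR 221-314), then neutrophils (546 px, 468-627), epithelial nuclei
#' (683 px, 524-858) and macrophages (1734 px, 1032-3152).  Areas are
#' drawn from per-class log-normal distributions fitted to the stated
#' median and quartiles.
#'
#' @param classes character vector of class names (labels are 1..m in this
#'   order).
#' @param frequencies per-class sampling frequencies (sum to 1).
#' @param area_median,area_q1,area_q3 per-class pixel-area median and
#'   quartiles.
#' @param shape_family `"ellipse"` (default), `"disc"` or `"star"`
#'   (star-convex irregular).
#' @param height,width image size in pixels.
#' @param n_instances instances per generated scene.
#' @param min_gap minimum gap between instances, px.
#' @param irregularity radial noise level for the `"star"` family.
#' @param seed optional default seed used by [generate_scene()].
#' @return a `population_spec` list.
#' @export
population_spec <- function(classes = c("lymphocyte", "neutrophil",
                                        "epithelial", "macrophage"),
                            frequencies = rep(1 / length(classes), length(classes)),
                            area_median = c(266, 546, 683, 1734),
                            area_q1 = c(221, 468, 524, 1032),
                            area_q3 = c(314, 627, 858, 3152),
                            shape_family = c("ellipse", "disc", "star"),
                            height = 512L, width = 512L,
                            n_instances = 60L, min_gap = 2L,
                            irregularity = 0.15, seed = NULL) {
  shape_family <- match.arg(shape_family)
  stopifnot(length(frequencies) == length(classes),
            length(area_median) == length(classes),
            length(area_q1) == length(classes),
            length(area_q3) == length(classes),
            all(area_median > 0), min_gap >= 0)
  if (abs(sum(frequencies) - 1) > 1e-8)
    stop("class frequencies must sum to 1", call. = FALSE)
  structure(list(classes = classes, frequencies = frequencies,
                 area_median = area_median, area_q1 = area_q1,
                 area_q3 = area_q3, shape_family = shape_family,
                 height = as.integer(height), width = as.integer(width),
                 n_instances = as.integer(n_instances),
                 min_gap = as.integer(min_gap),
                 irregularity = irregularity, seed = seed),
            class = "population_spec")
}

# log-normal (meanlog, sdlog) matching a median and quartiles
lognormal_params <- function(med, q1, q3) {
  list(meanlog = log(med), sdlog = log(q3 / q1) / (2 * qnorm(0.75)))
}

# ---- shape rasterizers: offsets (row, col) around an anchor ---------------

offsets_from_mask <- function(m) {
  pts <- mask_points(m)
  ctr <- round(colMeans(pts))
  cbind(pts[, 1] - ctr[1], pts[, 2] - ctr[2])
}

raster_ellipse_offsets <- function(area, ratio = 1, angle = 0) {
  draw <- function(a, b) {
    n <- 2L * as.integer(ceiling(a)) + 3L
    ctr <- (n + 1) / 2
    rr <- matrix(seq_len(n), n, n) - ctr
    cc <- t(matrix(seq_len(n), n, n)) - ctr
    u <- rr * cos(angle) + cc * sin(angle)
    v <- -rr * sin(angle) + cc * cos(angle)
    (u / a)^2 + (v / b)^2 <= 1
  }
  a <- sqrt(area * ratio / pi); b <- a / ratio
  m <- draw(a, b)
  s <- sqrt(area / max(sum(m), 1))   # one correction pass for raster bias
  m <- draw(a * s, b * s)
  offsets_from_mask(m)
}

raster_star_offsets <- function(area, irregularity = 0.15, n_vertices = 12L) {
  z <- rnorm(n_vertices)
  z <- (z + c(z[-1], z[1]) + c(z[n_vertices], z[-n_vertices])) / 3  # smooth
  radii_mult <- exp(irregularity * z)
  draw <- function(R) {
    rmax <- R * max(radii_mult)
    n <- 2L * as.integer(ceiling(rmax)) + 3L
    ctr <- (n + 1) / 2
    rr <- matrix(seq_len(n), n, n) - ctr
    cc <- t(matrix(seq_len(n), n, n)) - ctr
    theta <- atan2(cc, rr) %% (2 * pi)
    k <- theta / (2 * pi) * n_vertices
    k0 <- floor(k)
    frac <- k - k0
    i0 <- (as.integer(k0) %% n_vertices) + 1L
    i1 <- (i0 %% n_vertices) + 1L
    rad <- R * ((1 - frac) * radii_mult[i0] + frac * radii_mult[i1])
    sqrt(rr^2 + cc^2) <= rad
  }
  R <- sqrt(area / pi)
  m <- draw(R)
  s <- sqrt(area / max(sum(m), 1))
  m <- draw(R * s)
  offsets_from_mask(m)
}

shape_offsets <- function(spec, area) {
  switch(spec$shape_family,
    disc = offsets_from_mask(raster_disc(sqrt(area / pi))),
    ellipse = raster_ellipse_offsets(area, ratio = runif(1, 1, 1.6),
                                     angle = runif(1, 0, pi)),
    star = raster_star_offsets(area, spec$irregularity))
}

# square-dilate a set of offsets by `gap` pixels (claim footprint)
halo_offsets <- function(offs, gap) {
  if (gap <= 0) return(offs)
  r1 <- min(offs[, 1]) - gap; c1 <- min(offs[, 2]) - gap
  m <- matrix(FALSE, max(offs[, 1]) - r1 + 1L + gap, max(offs[, 2]) - c1 + 1L + gap)
  m[cbind(offs[, 1] - r1 + 1L, offs[, 2] - c1 + 1L)] <- TRUE
  for (i in seq_len(gap)) m <- dilate_mask(m, "square")
  pts <- mask_points(m)
  cbind(pts[, 1] + r1 - 1L, pts[, 2] + c1 - 1L)
}

#' Generate a synthetic ground-truth scene
#'
#' Samples classes and areas from the population spec, rasterizes one
#' shape per instance and places them uniformly at random without overlap
#' and with at least `min_gap` pixels between instances (larger instances
#' are placed first).  Generation is deterministic under a fixed seed.
#'
#' @param spec a [population_spec()].
#' @param seed integer seed (defaults to `spec$seed`); `NULL` uses the
#'   current RNG state.
#' @return an `annotated_scene` with a `"population_spec"` attribute.
#' @export
generate_scene <- function(spec, seed = spec$seed) {
  if (!is.null(seed)) set.seed(seed)
  m <- length(spec$classes)
  cls <- sample.int(m, spec$n_instances, replace = TRUE, prob = spec$frequencies)
  areas <- vapply(cls, function(k) {
    p <- lognormal_params(spec$area_median[k], spec$area_q1[k], spec$area_q3[k])
    max(4, rlnorm(1, p$meanlog, p$sdlog))
  }, numeric(1))
  ord <- order(-areas)
  h <- spec$height; w <- spec$width
  map <- matrix(0L, h, w)
  occ <- matrix(FALSE, h, w)
  class_of <- integer(spec$n_instances)
  placed <- 0L
  for (id in seq_len(spec$n_instances)) {
    k <- ord[id]
    offs <- shape_offsets(spec, areas[k])
    halo <- halo_offsets(offs, spec$min_gap)
    rmin <- min(offs[, 1]); rmax <- max(offs[, 1])
    cmin <- min(offs[, 2]); cmax <- max(offs[, 2])
    lo_r <- 1L - rmin; hi_r <- h - rmax
    lo_c <- 1L - cmin; hi_c <- w - cmax
    if (hi_r < lo_r || hi_c < lo_c)
      stop(sprintf("instance larger than the image; placed %d of %d",
                   placed, spec$n_instances), call. = FALSE)
    ok <- FALSE
    for (try in seq_len(300L)) {
      r0 <- resample1(lo_r:hi_r); c0 <- resample1(lo_c:hi_c)
      idx <- (offs[, 1] + r0) + (offs[, 2] + c0 - 1L) * h
      if (!any(occ[idx])) {
        map[idx] <- id
        hr <- halo[, 1] + r0; hc <- halo[, 2] + c0
        inside <- hr >= 1L & hr <= h & hc >= 1L & hc <= w
        occ[hr[inside] + (hc[inside] - 1L) * h] <- TRUE
        class_of[id] <- cls[k]
        placed <- placed + 1L
        ok <- TRUE
        break
      }
    }
    if (!ok)
      stop(sprintf("could not place instance %d of %d (image too crowded); achievable count: %d",
                   id, spec$n_instances, placed), call. = FALSE)
  }
  scene <- annotated_scene(map, setNames(class_of, seq_len(spec$n_instances)),
                           class_names = spec$classes)
  attr(scene, "population_spec") <- spec
  scene
}

#' Generate an index-aligned list of synthetic scenes
#'
#' @param spec a [population_spec()].
#' @param n_images number of scenes.
#' @param seed integer master seed; per-image seeds are derived from it.
#' @return list of `annotated_scene`.
#' @export
generate_dataset <- function(spec, n_images, seed = spec$seed) {
  if (!is.null(seed)) set.seed(seed)
  seeds <- sample.int(.Machine$integer.max, n_images)
  lapply(seeds, function(s) generate_scene(spec, seed = s))
}

#' Specify a prediction degradation
#'
#' @param dropout_rate probability that a ground-truth instance is missed.
#' @param spurious_rate expected number of spurious (false-positive)
#'   instances per image (Poisson).
#' @param erosion_px,dilation_px integer number of single-pixel erosions /
#'   dilations applied to each surviving instance (at most one of the two
#'   may be nonzero).
#' @param area_loss_frac target fraction of each instance's area removed
#'   by iterated single-pixel erosions (erosions are applied until the
#'   cumulative loss reaches this fraction); 0 disables.
#' @param jitter_px boundary jitter amplitude: each instance receives a
#'   uniform random morphological offset in `-jitter_px..jitter_px`
#'   (negative = erosions, positive = dilations) plus a uniform random
#'   translation of the same amplitude.
#' @param misclass_rate probability that a surviving instance's class is
#'   flipped to a uniformly random other class.
#' @param seed optional default seed for [degrade()].
#' @return a `degradation_spec` list.
#' @export
degradation_spec <- function(dropout_rate = 0, spurious_rate = 0,
                             erosion_px = 0L, dilation_px = 0L,
                             area_loss_frac = 0, jitter_px = 0L,
                             misclass_rate = 0, seed = NULL) {
  stopifnot(dropout_rate >= 0, dropout_rate <= 1,
            misclass_rate >= 0, misclass_rate <= 1,
            spurious_rate >= 0, erosion_px >= 0, dilation_px >= 0,
            area_loss_frac >= 0, area_loss_frac < 1, jitter_px >= 0)
  if (erosion_px > 0 && dilation_px > 0)
    stop("at most one of erosion_px / dilation_px may be nonzero", call. = FALSE)
  structure(list(dropout_rate = dropout_rate, spurious_rate = spurious_rate,
                 erosion_px = as.integer(erosion_px),
                 dilation_px = as.integer(dilation_px),
                 area_loss_frac = area_loss_frac,
                 jitter_px = as.integer(jitter_px),
                 misclass_rate = misclass_rate, seed = seed),
            class = "degradation_spec")
}

# apply a signed morphological offset (negative erode, positive dilate)
morph_k <- function(m, k, kernel = "cross") {
  if (k == 0) return(m)
  for (i in seq_len(abs(k)))
    m <- if (k < 0) erode_mask(m, kernel) else dilate_mask(m, kernel)
  m
}

# linear in-image indices of a crop mask placed at offset (r0, c0)
crop_indices <- function(crop_mask, r0, c0, h, w) {
  pts <- mask_points(crop_mask)
  if (!nrow(pts)) return(integer(0))
  r <- pts[, 1] + r0; c <- pts[, 2] + c0
  inside <- r >= 1L & r <= h & c >= 1L & c <= w
  r[inside] + (c[inside] - 1L) * h
}

#' Degrade a ground-truth scene into a synthetic prediction
#'
#' Each ground-truth instance is independently dropped with
#' `dropout_rate`; survivors receive the configured boundary degradations
#' and have their class flipped with `misclass_rate`; spurious instances
#' (drawn from the smallest-area class's distribution) are added on the
#' background.  If degraded masks collide, earlier-painted pixels win
#' (instance IDs are processed in increasing order), keeping the
#' prediction map single-valued.
#'
#' @param scene a ground-truth `annotated_scene`.
#' @param spec a [degradation_spec()].
#' @param seed integer seed (defaults to `spec$seed`).
#' @return list with `scene` (the prediction, instance IDs inherited from
#'   the ground truth, spurious IDs appended) and `log` (one row per
#'   ground-truth instance plus one per spurious instance).
#' @export
degrade <- function(scene, spec, seed = spec$seed) {
  if (!is.null(seed)) set.seed(seed)
  h <- scene$height; w <- scene$width
  px <- instance_index_list(scene$instance_map)
  ids <- as.integer(names(px))
  m_classes <- seq_along(if (!is.null(scene$class_names)) scene$class_names
                         else seq_len(max(c(scene$class_of, 1L))))
  map <- matrix(0L, h, w)
  class_of <- integer(0)
  log_rows <- list()
  margin <- spec$jitter_px + spec$dilation_px + 2L
  for (i in seq_along(ids)) {
    id <- ids[i]; id_chr <- as.character(id)
    cl <- unname(scene$class_of[id_chr])
    dropped <- runif(1) < spec$dropout_rate
    erode_n <- 0L; dilate_n <- 0L; jit_k <- 0L; dr <- 0L; dc <- 0L
    new_cl <- cl; emptied <- FALSE
    if (!dropped) {
      cr <- crop_instance(px[[id_chr]], h, w, margin = margin)
      msk <- cr$mask
      area0 <- sum(msk)
      if (spec$erosion_px > 0) {
        erode_n <- spec$erosion_px
        msk <- morph_k(msk, -erode_n)
      } else if (spec$dilation_px > 0) {
        dilate_n <- spec$dilation_px
        msk <- morph_k(msk, dilate_n)
      } else if (spec$area_loss_frac > 0) {
        while (any(msk) && sum(msk) > (1 - spec$area_loss_frac) * area0) {
          msk <- erode_mask(msk, "cross")
          erode_n <- erode_n + 1L
        }
      }
      if (spec$jitter_px > 0 && any(msk)) {
        jit_k <- sample(-spec$jitter_px:spec$jitter_px, 1L)
        msk <- morph_k(msk, jit_k)
        dr <- sample(-spec$jitter_px:spec$jitter_px, 1L)
        dc <- sample(-spec$jitter_px:spec$jitter_px, 1L)
        msk <- shift_mask(msk, dr, dc)
      }
      if (spec$misclass_rate > 0 && runif(1) < spec$misclass_rate &&
          length(m_classes) > 1) {
        new_cl <- resample1(setdiff(m_classes, cl))
      }
      emptied <- !any(msk)
      if (!emptied) {
        idx <- crop_indices(msk, cr$r0, cr$c0, h, w)
        idx <- idx[map[idx] == 0L]  # earlier-painted pixels win
        map[idx] <- id
        class_of[id_chr] <- new_cl
      }
    }
    log_rows[[i]] <- data.frame(
      id = id, spurious = FALSE, dropped = dropped || emptied,
      erode_px = erode_n, dilate_px = dilate_n, jitter_k = jit_k,
      shift_r = dr, shift_c = dc, class_from = cl, class_to = new_cl,
      emptied = emptied)
  }
  n_spur <- if (spec$spurious_rate > 0) rpois(1, spec$spurious_rate) else 0L
  if (n_spur > 0) {
    pop <- attr(scene, "population_spec")
    draw_area <- if (!is.null(pop)) {
      k <- which.min(pop$area_median)
      p <- lognormal_params(pop$area_median[k], pop$area_q1[k], pop$area_q3[k])
      function() max(4, rlnorm(1, p$meanlog, p$sdlog))
    } else {
      obs <- instance_areas(scene)
      function() if (length(obs)) as.numeric(sample(obs, 1L)) else 100
    }
    next_id <- max(c(0L, ids)) + 1L
    free <- map == 0L & scene$instance_map == 0L
    for (s in seq_len(n_spur)) {
      offs <- offsets_from_mask(raster_disc(sqrt(draw_area() / pi)))
      for (try in seq_len(100L)) {
        r0 <- sample.int(h, 1L); c0 <- sample.int(w, 1L)
        r <- offs[, 1] + r0; c <- offs[, 2] + c0
        if (any(r < 1L | r > h | c < 1L | c > w)) next
        idx <- r + (c - 1L) * h
        if (all(free[idx])) {
          map[idx] <- next_id
          free[idx] <- FALSE
          cl_s <- resample1(m_classes)
          class_of[as.character(next_id)] <- cl_s
          log_rows[[length(log_rows) + 1L]] <- data.frame(
            id = next_id, spurious = TRUE, dropped = FALSE,
            erode_px = 0L, dilate_px = 0L, jitter_k = 0L,
            shift_r = 0L, shift_c = 0L, class_from = NA_integer_,
            class_to = cl_s, emptied = FALSE)
          next_id <- next_id + 1L
          break
        }
      }
    }
  }
  keep <- unique(map[map > 0L])
  pred <- annotated_scene(map, class_of[as.character(sort(keep))],
                          class_names = scene$class_names)
  list(scene = pred, log = do.call(rbind, log_rows))
}

#' Specify a panel of simulated raters
#'
#' @param n_raters number of raters (>= 2).
#' @param jitter_px per-rater boundary jitter amplitude (recycled).
#' @param bias_px per-rater systematic boundary bias in pixels (negative =
#'   erosion tendency, positive = dilation tendency; recycled).
#' @param seed optional default seed.
#' @return a `rater_spec` list.
#' @export
rater_spec <- function(n_raters = 3L, jitter_px = 1L, bias_px = 0L, seed = NULL) {
  if (n_raters < 2) stop("need at least two raters", call. = FALSE)
  structure(list(n_raters = as.integer(n_raters),
                 jitter_px = rep_len(as.integer(jitter_px), n_raters),
                 bias_px = rep_len(as.integer(bias_px), n_raters),
                 seed = seed),
            class = "rater_spec")
}

#' Simulate independent rater annotations of one scene
#'
#' Each rater re-annotates every instance with an independent boundary
#' jitter (random morphological offset plus translation, amplitude
#' `jitter_px`) on top of the rater's systematic erosion/dilation bias.
#' Instance identity is preserved: rater scenes keep the ground-truth IDs.
#'
#' @param scene an `annotated_scene`.
#' @param spec a [rater_spec()].
#' @param seed integer seed (defaults to `spec$seed`).
#' @return list of `annotated_scene`, one per rater.
#' @export
simulate_raters <- function(scene, spec, seed = spec$seed) {
  if (!is.null(seed)) set.seed(seed)
  h <- scene$height; w <- scene$width
  px <- instance_index_list(scene$instance_map)
  lapply(seq_len(spec$n_raters), function(r) {
    jit <- spec$jitter_px[r]; bias <- spec$bias_px[r]
    map <- matrix(0L, h, w)
    kept <- character(0)
    margin <- jit + max(0L, bias) + 2L
    for (id_chr in names(px)) {
      cr <- crop_instance(px[[id_chr]], h, w, margin = margin)
      k <- bias + if (jit > 0) sample(-jit:jit, 1L) else 0L
      msk <- morph_k(cr$mask, k)
      if (jit > 0 && any(msk))
        msk <- shift_mask(msk, sample(-jit:jit, 1L), sample(-jit:jit, 1L))
      if (any(msk)) {
        idx <- crop_indices(msk, cr$r0, cr$c0, h, w)
        idx <- idx[map[idx] == 0L]
        map[idx] <- as.integer(id_chr)
        kept <- c(kept, id_chr)
      }
    }
    annotated_scene(map, scene$class_of[kept], class_names = scene$class_names)
  })
}
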