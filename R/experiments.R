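# ---- reproducible experiment pipelines ------------------------------------

# boxplot-style summary: median, quartiles, min/max excluding Tukey
# outliers (1.5 IQR fences)
five_stats <- function(x) {
  q <- quantile(x, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  fence_lo <- q[1] - 1.5 * (q[3] - q[1])
  fence_hi <- q[3] + 1.5 * (q[3] - q[1])
  inl <- x[x >= fence_lo & x <= fence_hi]
  data.frame(n = length(x), median = q[2], q1 = q[1], q3 = q[3],
             min = if (length(inl)) min(inl) else NA_real_,
             max = if (length(inl)) max(inl) else NA_real_,
             n_outliers = length(x) - length(inl))
}

new_report <- function(name, provenance, summary, raw = NULL, extra = list()) {
  structure(c(list(name = name, provenance = provenance,
                   summary = summary, raw = raw), extra),
            class = "experiment_report")
}

#' @export
print.experiment_report <- function(x, ...) {
  cat(sprintf("<experiment_report> %s\n", x$name))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Write an experiment report's tables and provenance to disk
#'
#' Writes `<name>_summary.csv`, `<name>_raw.csv` (when raw records exist)
#' and `<name>_provenance.json` under `dir`.
#'
#' @param report an `experiment_report`.
#' @param dir output directory (created if missing).
#' @return invisibly, the paths written.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  p <- file.path(dir, paste0(report$name, "_summary.csv"))
  write.csv(report$summary, p, row.names = FALSE)
  paths <- c(paths, p)
  if (!is.null(report$raw)) {
    p <- file.path(dir, paste0(report$name, "_raw.csv"))
    write.csv(report$raw, p, row.names = FALSE)
    paths <- c(paths, p)
  }
  p <- file.path(dir, paste0(report$name, "_provenance.json"))
  jsonlite::write_json(report$provenance, p, auto_unbox = TRUE, null = "null")
  invisible(c(paths, p))
}

#' Inter-rater agreement experiment
#'
#' For every unordered pair of raters, matches annotations in the loosest
#' sense (any overlap, largest IoU wins) and records each matched pair's
#' IoU and Hausdorff distance together with the first rater's instance
#' area.  IoU is summarized per area bin, and an ordinary least-squares
#' log-linear fit of log10(HD) on IoU is reported over pairs with HD > 0
#' (HD = 0 pairs are excluded and counted).
#'
#' @param raters list (>= 2) of `annotated_scene` objects annotating the
#'   same image, or a list of such lists (one per image).
#' @param area_bins numeric cut points for the instance-area bins, px.
#' @return an `experiment_report` with per-bin IoU statistics, the raw
#'   per-pair records and the regression fit (`$fit`).
#' @export
experiment_interrater <- function(raters,
                                  area_bins = c(0, 200, 400, 700, 1100, Inf)) {
  if (inherits(raters[[1]], "annotated_scene")) raters <- list(raters)
  if (any(vapply(raters, length, 1L) < 2))
    stop("need at least two raters per image", call. = FALSE)
  rows <- list()
  for (img in seq_along(raters)) {
    rs <- raters[[img]]
    for (a in seq_len(length(rs) - 1L)) for (b in seq((a + 1L), length(rs))) {
      mt <- match_by_overlap(rs[[a]], rs[[b]])
      if (!nrow(mt$pairs)) next
      areas <- instance_areas(rs[[a]])
      hd <- pair_hausdorff(rs[[a]], rs[[b]], mt$pairs)
      rows[[length(rows) + 1L]] <- data.frame(
        image = img, rater_a = a, rater_b = b,
        id_a = mt$pairs$gt_id, id_b = mt$pairs$pred_id,
        area_px = as.integer(areas[as.character(mt$pairs$gt_id)]),
        iou = mt$pairs$iou, hd = hd)
    }
  }
  raw <- do.call(rbind, rows)
  raw$area_bin <- cut(raw$area_px, area_bins, include.lowest = TRUE)
  summary <- do.call(rbind, lapply(split(raw, raw$area_bin, drop = TRUE),
                                   function(d) cbind(area_bin = d$area_bin[1],
                                                     five_stats(d$iou))))
  pos <- raw[raw$hd > 0, ]
  fit <- if (nrow(pos) >= 3) lm(log10(hd) ~ iou, data = pos) else NULL
  new_report("interrater",
             list(n_images = length(raters),
                  n_pairs = nrow(raw), n_hd_zero = sum(raw$hd == 0),
                  area_bins = area_bins),
             summary, raw,
             extra = list(fit = fit,
                          slope = if (!is.null(fit)) unname(coef(fit)[2]) else NA_real_))
}

#' Single-pixel perturbation experiment
#'
#' Runs [perturbation_sweep()] over the scenes and summarizes the IoU of
#' each perturbation per class (median, quartiles, Tukey-fenced min/max).
#'
#' @param scenes an `annotated_scene` or list thereof.
#' @param kinds perturbation kinds, see [perturbation_sweep()].
#' @param kernel structuring element, `"cross"` or `"square"`.
#' @return an `experiment_report`; `$summary` has one row per
#'   (class, perturbation).
#' @export
experiment_perturbation <- function(scenes,
                                    kinds = c("erode1", "dilate1", "shift1"),
                                    kernel = "cross") {
  if (!length(kinds)) {
    return(new_report("perturbation", list(kinds = character(0), kernel = kernel),
                      data.frame()))
  }
  raw <- perturbation_sweep(scenes, kinds, kernel)
  grp <- split(raw, list(raw$class_label, raw$perturbation), drop = TRUE)
  summary <- do.call(rbind, lapply(grp, function(d)
    cbind(class_label = d$class_label[1], perturbation = d$perturbation[1],
          five_stats(d$iou_after))))
  rownames(summary) <- NULL
  new_report("perturbation",
             list(kinds = kinds, kernel = kernel,
                  n_instances = length(unique(paste(raw$scene, raw$instance_id)))),
             summary, raw)
}

#' Detection-error vs segmentation-error tradeoff experiment
#'
#' Builds two degraded predictions of the same ground truth — one with
#' detection dropout and perfect segmentation, one with full detection and
#' a fixed fraction of each instance's area eroded away — and evaluates
#' both with PQ (both aggregations) and with the separated metrics
#' (detection F1, balanced accuracy, median HD).  PQ typically ranks the
#' dropout arm above the erosion arm while detection F1 ranks them the
#' opposite way.
#'
#' @param gts ground-truth `annotated_scene` or list thereof.
#' @param dropout_level dropout rate for the detection-error arm.
#' @param erosion_fraction area fraction removed per instance in the
#'   segmentation-error arm.
#' @param seed integer seed for the degradations.
#' @param radius centroid-matching radius for the separated metrics.
#' @return an `experiment_report`; `$summary` has one row per arm and
#'   `$ranks` the sum-of-ranks table over (aPQ, detection F1).
#' @export
experiment_error_tradeoff <- function(gts, dropout_level = 0.4,
                                      erosion_fraction = 0.3, seed = NULL,
                                      radius = 15) {
  if (inherits(gts, "annotated_scene")) gts <- list(gts)
  if (!is.null(seed)) set.seed(seed)
  seeds <- sample.int(.Machine$integer.max, 2L * length(gts))
  det_arm <- lapply(seq_along(gts), function(i)
    degrade(gts[[i]], degradation_spec(dropout_rate = dropout_level),
            seed = seeds[i])$scene)
  seg_arm <- lapply(seq_along(gts), function(i)
    degrade(gts[[i]], degradation_spec(area_loss_frac = erosion_fraction),
            seed = seeds[length(gts) + i])$scene)
  ev_det <- evaluate_dataset(gts, det_arm, radius = radius)
  ev_seg <- evaluate_dataset(gts, seg_arm, radius = radius)
  row_of <- function(arm, ev) data.frame(
    arm = arm, apq = ev$pq$apq, mpq = ev$pq$mpq,
    detection_f1 = ev$detection_f1, balanced_accuracy = ev$balanced_accuracy,
    median_hd = ev$median_hd)
  summary <- rbind(row_of("detection_error", ev_det),
                   row_of("segmentation_error", ev_seg))
  scores <- as.matrix(summary[, c("apq", "detection_f1")])
  rownames(scores) <- summary$arm
  ranks <- sum_of_ranks(scores, higher_is_better = c(TRUE, TRUE))
  new_report("error_tradeoff",
             list(dropout_level = dropout_level,
                  erosion_fraction = erosion_fraction, seed = seed,
                  n_instances = sum(vapply(gts, function(s) length(s$class_of), 1L))),
             summary,
             extra = list(ranks = ranks, eval_detection = ev_det,
                          eval_segmentation = ev_seg))
}

#' Misclassification-vs-missed-detection penalty experiment
#'
#' For sampled ground-truth instances, constructs two otherwise perfect
#' predictions: one where the instance is detected with perfect overlap
#' but the wrong class, and one where it is simply missing.  Reports the
#' aPQ and mPQ of both variants and their deltas; the wrong-class variant
#' is penalized at least as hard (strictly harder whenever the scene
#' contains at least one other correctly predicted instance).
#'
#' @param gts ground-truth `annotated_scene` or list thereof (>= 2 classes).
#' @param n_sample number of instances to sample (0 gives an empty report).
#' @param seed integer seed for the sampling.
#' @return an `experiment_report`; `$summary` has one row per sampled
#'   instance with columns `apq_misclassified`, `apq_missed`, `delta_apq`,
#'   `delta_mpq`.
#' @export
experiment_misclassification_penalty <- function(gts, n_sample = 10L, seed = NULL) {
  if (inherits(gts, "annotated_scene")) gts <- list(gts)
  if (!is.null(seed)) set.seed(seed)
  all_classes <- sort(unique(unlist(lapply(gts, scene_classes))))
  if (length(all_classes) < 2)
    stop("misclassification penalty needs at least two classes", call. = FALSE)
  pool <- do.call(rbind, lapply(seq_along(gts), function(i)
    data.frame(image = i, id = scene_ids(gts[[i]]))))
  if (n_sample == 0 || !nrow(pool)) {
    return(new_report("misclassification_penalty",
                      list(n_sample = 0L, seed = seed), data.frame()))
  }
  take <- pool[sample.int(nrow(pool), min(n_sample, nrow(pool))), , drop = FALSE]
  rows <- lapply(seq_len(nrow(take)), function(k) {
    i <- take$image[k]; id <- take$id[k]
    gt <- gts[[i]]
    cl <- unname(gt$class_of[as.character(id)])
    wrong <- resample1(setdiff(all_classes, cl))
    mis <- gt
    mis$class_of[as.character(id)] <- wrong
    missed_map <- gt$instance_map
    missed_map[missed_map == id] <- 0L
    missed <- annotated_scene(missed_map,
                              gt$class_of[names(gt$class_of) != as.character(id)],
                              class_names = gt$class_names)
    preds_mis <- gts; preds_mis[[i]] <- mis
    preds_missed <- gts; preds_missed[[i]] <- missed
    agg_mis <- aggregate_pq(gts, preds_mis, classes = all_classes)
    agg_missed <- aggregate_pq(gts, preds_missed, classes = all_classes)
    data.frame(image = i, id = id, class_from = cl, class_to = wrong,
               apq_misclassified = agg_mis$apq, apq_missed = agg_missed$apq,
               mpq_misclassified = agg_mis$mpq, mpq_missed = agg_missed$mpq,
               delta_apq = agg_missed$apq - agg_mis$apq,
               delta_mpq = agg_missed$mpq - agg_mis$mpq)
  })
  summary <- do.call(rbind, rows)
  new_report("misclassification_penalty",
             list(n_sample = nrow(summary), seed = seed,
                  classes = all_classes),
             summary)
}
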