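#!/usr/bin/env Rscript
# Simulated inter-rater study: three raters re-annotate the same scenes
# with 1 px boundary jitter and individual erosion/dilation tendencies.
# Matched annotation pairs (any overlap, largest IoU) show that IoU between
# equally plausible annotations drops well below the strict 0.5 matching
# threshold for small nuclei, while Hausdorff distance stays small.

suppressPackageStartupMessages(library(nucleval))
dir.create("results", showWarnings = FALSE)

spec <- population_spec(height = 1000L, width = 1000L, n_instances = 250L)
scenes <- generate_dataset(spec, 2, seed = 31415)
raters <- lapply(seq_along(scenes), function(i)
  simulate_raters(scenes[[i]], rater_spec(3, jitter_px = 1, bias_px = c(-1, 0, 1)),
                  seed = 1000 + i))

rep <- experiment_interrater(raters, area_bins = c(0, 250, 450, 800, 1400, Inf))
write.csv(rep$summary, "results/03_interrater_iou_by_area.csv", row.names = FALSE)
write.csv(rep$raw, "results/03_interrater_pairs.csv", row.names = FALSE)

cat("Inter-rater IoU by instance area bin:\n")
print(rep$summary, row.names = FALSE)
cat(sprintf("\n%d matched pairs; %d with identical contours (HD = 0).\n",
            nrow(rep$raw), rep$provenance$n_hd_zero))
cat(sprintf("Log-linear fit log10(HD) ~ IoU: slope %.2f (negative: higher IoU, smaller HD).\n",
            rep$slope))
cat(sprintf("Fraction of matched pairs under the 0.5 IoU matching threshold: %.3f\n",
            mean(rep$raw$iou <= 0.5)))
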