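#!/usr/bin/env Rscript
# How much IoU does a single-pixel boundary error cost?  Applies one-pixel
# erosion, dilation and vertical shift to every instance of the synthetic
# population (plus the half-resolution variants) and summarizes IoU per
# class — small classes pay far more for the same one-pixel error, and
# dilation always costs slightly less than erosion.

suppressPackageStartupMessages(library(nucleval))
dir.create("results", showWarnings = FALSE)

spec <- population_spec(height = 1400L, width = 1400L, n_instances = 500L)
scenes <- generate_dataset(spec, 4, seed = 20260924)

rep <- experiment_perturbation(scenes,
                               kinds = c("erode1", "dilate1", "shift1",
                                         "down2_erode1", "down2_dilate1"),
                               kernel = "cross")
rep$summary$class <- spec$classes[rep$summary$class_label]
write.csv(rep$summary, "results/02_perturbation_summary.csv", row.names = FALSE)
write.csv(rep$raw, "results/02_perturbation_records.csv", row.names = FALSE)

cat("Median IoU after each single-pixel perturbation:\n")
wide <- reshape(rep$summary[, c("class", "perturbation", "median")],
                idvar = "class", timevar = "perturbation", direction = "wide")
print(wide, row.names = FALSE)
lym <- rep$summary[rep$summary$class == "lymphocyte", ]
cat(sprintf("\nLymphocytes: erosion median %.2f vs dilation %.2f at full resolution;",
            lym$median[lym$perturbation == "erode1"],
            lym$median[lym$perturbation == "dilate1"]))
cat(sprintf(" %.2f vs %.2f after 2x downscaling.\n",
            lym$median[lym$perturbation == "down2_erode1"],
            lym$median[lym$perturbation == "down2_dilate1"]))
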