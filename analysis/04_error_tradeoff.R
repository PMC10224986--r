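#!/usr/bin/env Rscript
# Can PQ prefer a predictor that misses 40% of all nuclei over one that
# finds every nucleus but draws each boundary ~30% too small?  Yes — and
# the separated metrics (detection F1, balanced accuracy, Hausdorff
# distance) plus a sum-of-ranks aggregation make the disagreement explicit.

suppressPackageStartupMessages(library(nucleval))
dir.create("results", showWarnings = FALSE)

spec <- population_spec(classes = c("lymphocyte", "epithelial"),
                        frequencies = c(0.5, 0.5),
                        area_median = c(266, 683), area_q1 = c(221, 524),
                        area_q3 = c(314, 858),
                        height = 1500L, width = 1500L, n_instances = 800L)
gt <- generate_scene(spec, seed = 27182)

rep <- experiment_error_tradeoff(gt, dropout_level = 0.4,
                                 erosion_fraction = 0.3, seed = 618)
write.csv(rep$summary, "results/04_error_tradeoff.csv", row.names = FALSE)
write.csv(data.frame(arm = names(rep$ranks$rank_sums),
                     rank_sum = rep$ranks$rank_sums),
          "results/04_error_tradeoff_ranks.csv", row.names = FALSE)

cat("Two degraded predictions of the same 800-nucleus scene:\n\n")
print(rep$summary, row.names = FALSE)
cat(sprintf("\nPQ ranks the 40%%-dropout arm ABOVE the 30%%-erosion arm (%.3f > %.3f),",
            rep$summary$apq[1], rep$summary$apq[2]))
cat(sprintf("\nwhile detection F1 orders them the other way (%.3f < %.3f).\n",
            rep$summary$detection_f1[1], rep$summary$detection_f1[2]))
cat("\nSum of ranks over (aPQ, detection F1):\n")
print(rep$ranks$rank_sums)
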