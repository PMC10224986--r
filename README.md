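# nucleval

Evaluation metrics and diagnostics for **nucleus instance segmentation and
classification** (ISC) in digital pathology.

Challenges and papers in this field rank algorithms with **Panoptic
Quality (PQ)**: predicted and ground-truth nuclei of the same class are
matched by the strict rule IoU > 0.5, and then

```
RQ = |TP| / (|TP| + ½|FP| + ½|FN|)        object-level F1 ("recognition quality")
SQ = Σ IoU(g,p) / |TP|                    mean matched IoU ("segmentation quality")
PQ = SQ · RQ = Σ IoU(g,p) / (|TP| + ½|FP| + ½|FN|)
```

with two non-equivalent multi-class aggregations in circulation: **aPQ**
(average per-image, per-class PQ) and **mPQ** (per-class PQ pooled over the
dataset, then averaged). For objects as small as nuclei (a lymphocyte is
~266 px at 0.25 µm/px) this construction is fragile: one pixel of boundary
error costs 8–20% IoU, underestimation costs more than overestimation
(IoU⁻ = (TP−n)/(TP+n) vs IoU⁺ = TP/(TP+n)), plausible inter-annotator
variability falls below the 0.5 matching threshold, and a well-segmented
nucleus with the wrong class is penalized harder than a missed one.

`nucleval` implements the full PQ stack **and** the diagnostics that expose
these failure modes, plus the separated evaluation it argues for: detection
F1 on "nucleus vs background" (any-overlap or greedy centroid matching),
balanced accuracy on the detected nuclei, Hausdorff-distance summaries, and
sum-of-ranks aggregation. A synthetic nuclei-scene generator with
class-specific log-normal area distributions and controllable degradations
(dropout, boundary erosion/dilation/jitter, misclassification, spurious
detections) makes every analysis reproducible without any external dataset.

## Worked example

```r
library(nucleval)

spec <- population_spec(height = 600L, width = 600L, n_instances = 90L)
gt   <- generate_scene(spec, seed = 7)
pred <- degrade(gt, degradation_spec(dropout_rate = 0.15, jitter_px = 1,
                                     misclass_rate = 0.1, spurious_rate = 4),
                seed = 8)$scene

ev <- evaluate_dataset(list(gt), list(pred))
ev$pq
#> <aggregate_pq> aPQ = 0.7146 (n = 1 images), mPQ = 0.7146 (m = 4 classes)
sprintf("detection F1 = %.3f | balanced accuracy = %.3f | median HD = %.2f px",
        ev$detection_f1, ev$balanced_accuracy, ev$median_hd)
#> "detection F1 = 0.912 | balanced accuracy = 0.892 | median HD = 2.00 px"
ev$confusion
#>             pred
#> gt           background  1  2  3  4
#>   background          0  2  1  0  0
#>   1                   3 21  0  0  1
#>   2                   3  0 14  2  1
#>   3                   5  0  2 21  0
#>   4                   1  1  0  1 14
```

The prediction dropped ~15% of nuclei, jittered every boundary by ~1 px and
flipped ~10% of classes. PQ compresses all of that into 0.71; the separated
metrics show what actually happened: detection is fine (F1 0.91),
classification is fine (balanced accuracy 0.89), and the segmentations sit
~2 px from the reference contours — comfortably within inter-annotator
variability, which is exactly the information PQ hides.

## The analyses

Numbered drivers under `analysis/` regenerate every result table into
`results/` (all are seeded):

| script | what it shows |
|---|---|
| `01_simulate_population.R` | the generator hits the published per-class area statistics (medians 266/546/683/1734 px) |
| `02_perturbation_analysis.R` | IoU cost of single-pixel erosion/dilation/shift per class, at full and half resolution |
| `03_interrater_agreement.R` | simulated 1 px rater jitter: IoU falls with object size while HD stays at 1–3 px; log-linear IoU–HD fit |
| `04_error_tradeoff.R` | missing 40% of nuclei out-scores eroding every nucleus by ~30% area under PQ; detection F1 disagrees |
| `05_misclassification_penalty.R` | wrong-class detection costs strictly more aPQ than a missed detection, diluting with scene size |

Run them from the repository root, e.g. `Rscript analysis/04_error_tradeoff.R`.

## Scene I/O

Scenes are paired 16-bit single-channel TIFF label maps (instance IDs +
class labels, 0 = background) with an optional JSON sidecar
(`read_scene()` / `write_scene()`), with adapters for per-instance
binary-mask directories (`read_mask_dir()`) and polygon-CSV exports
(`read_polygon_csv()`). An optional "ambiguous region" mask excludes
annotation-free zones from all matching.
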