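---
title: "Evaluating nucleus instance segmentation and classification: PQ, its pitfalls, and separated metrics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating nucleus instance segmentation and classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The task and the metric

Nucleus instance segmentation and classification (ISC) asks an algorithm to
delineate every nucleus in a histopathology image and assign it a class
(epithelial, lymphocyte, neutrophil, macrophage, ...). The dominant
evaluation metric, Panoptic Quality (PQ), first matches predicted to
ground-truth instances of the same class by the strict rule IoU $> 0.5$
(at this threshold a partner is necessarily unique, since two distinct
predictions cannot each cover more than half of the same union), then
computes, per class $c$ and image $i$:

$$RQ = \frac{|TP|}{|TP| + \tfrac12|FP| + \tfrac12|FN|}, \qquad
SQ = \frac{\sum_{(g,p)\in TP} IoU(g,p)}{|TP|}, \qquad
PQ = SQ \times RQ = \frac{\sum_{(g,p)\in TP} IoU(g,p)}{|TP| + \tfrac12|FP| + \tfrac12|FN|}.$$

Two aggregation schemes are both in active use, and they are not
equivalent. `aggregate_pq()` computes both:

* **aPQ** averages $PQ_{c,i}$ over the $m_i$ classes present in image $i$,
  then averages the per-image values over the $n$ images.
* **mPQ** pools the TP/FP/FN counts and IoU sums per class over the whole
  dataset before forming one $PQ_c$ per class, then averages over classes.

The definition leaves an edge case open: when a class occurs in only one of
ground truth and prediction there are no matches, so SQ is undefined. We
follow the de-facto challenge practice: such a class contributes
$PQ_{c,i} = 0$; a class absent from both sides of an image is excluded from
$m_i$. Undefined values are kept as `NA` — never silently coerced to 0 —
and the two coercions that do occur during aggregation (an image with no
instances at all, a pooled class with no objects anywhere) emit warnings.

## Why PQ misleads for small objects

The package's diagnostics quantify four failure modes.

**IoU is asymmetric and brutal on small objects.** Starting from a perfect
prediction of a TP-pixel object, adding $n$ background pixels gives
$IoU^+ = TP/(TP+n)$, while displacing $n$ true-positive pixels outside the
object gives $IoU^- = (TP-n)/(TP+n)$: underestimation is punished more than
overestimation of the same magnitude (`iou_over()`, `iou_under()`). For a
150 px object and $n = 50$ these are 0.75 and 0.50. Because typical nuclei
are only a few hundred pixels at 0.25 µm/px, a *single-pixel* boundary
error already costs 8–20% IoU (`perturbation_sweep()`), and the cost
doubles at half resolution (`downscale2()`).

**The strict 0.5 threshold discards plausible annotations.** Simulated
raters (`simulate_raters()`) disagreeing by ~1 px of boundary jitter
produce matched pairs whose IoU drops toward and below 0.5 for the
smallest nuclei, while their Hausdorff distance stays at 1–3 px
(`experiment_interrater()`). Under PQ those would count as detection
failures.

**Misclassification is punished harder than missing the object.** PQ is
computed per class with an implicit background: a perfectly segmented
nucleus with the wrong class is a false positive for the wrong class *and*
a false negative for the right one, whereas a missed nucleus is only a
false negative. `experiment_misclassification_penalty()` measures the aPQ
gap; it is strictly positive whenever at least one other instance is
correctly predicted. (In the degenerate single-instance scene the two
variants tie at aPQ = 0 under the aggregation rules above — the strict
inequality needs context instances.)

**RQ and SQ trade off invisibly.** `experiment_error_tradeoff()` rebuilds
the headline inversion: on an ~800-nucleus two-class scene, a prediction
missing 40% of all nuclei (perfect segmentation otherwise) out-scores a
prediction that detects everything but erodes each nucleus by ~30% of its
area (2–3 px of erosion), while detection F1 ranks the two arms the other
way around.

## The recommended separated evaluation

Instead of one catch-all number, the package scores the three sub-tasks
separately and, when one ranking is needed, combines *ranks*, not scores:

* **Detection**: class-agnostic matching — any-overlap with largest-IoU
  tie-break (`match_by_overlap()`) or greedy minimal centroid distance
  within a tolerance radius (`match_by_centroid()`) — then object-level F1
  on "nucleus vs background" (`detection_f1()`).
* **Classification**: `balanced_accuracy()` (mean per-class recall) on the
  $m \times m$ matched submatrix of the object-level confusion matrix
  (`confusion_isc()`), whose extra background row/column holds spurious
  and missed detections and whose top-left cell is structurally empty.
* **Segmentation**: Hausdorff distance between matched contours
  (`hausdorff()`), summarized by its median.
* **Aggregation**: `sum_of_ranks()` with mid-rank ties.

## Parameters that matter

| parameter | default | why |
|---|---|---|
| IoU matching threshold | 0.5 (strict `>`) | printed definition; uniqueness guarantee requires ≥ 0.5, so lower values are rejected |
| centroid-match radius | 15 px at 0.25 µm/px | on the order of one nucleus radius (class areas 266–1734 px imply radii ≈ 9–23 px); configurable |
| structuring element | 3×3 cross (4-connectivity) | minimal isotropic single-pixel kernel; 3×3 square available, recorded per sweep |
| shift direction | +1 row (down) | IoU is direction-invariant for this analysis; a fixed sign keeps runs reproducible |
| downscaling | subsample odd (1-based) rows/columns | nearest-neighbour keeps label semantics; pooling would invent mixed labels |
| area bins, outlier fences | Tukey 1.5·IQR | the usual boxplot convention for min–max excluding outliers |

Coordinates are 1-based `(row, col)` from the top-left, the R matrix
convention; contours are instance pixels with a 4-neighbour outside the
instance (image borders count as outside), and Hausdorff distances are
Euclidean between pixel centers. Published HD values for such data could
in principle be computed on polygon vertices instead; pixel contours are
assumed and fixed here for reproducibility.

## What the synthetic generator does and does not emulate

`generate_scene()` draws class labels at user-set frequencies (uniform by
default) and areas from per-class log-normal distributions fitted to a
median and quartiles — the log-normal is chosen for positivity and right
skew, matching the published per-class area statistics (medians
266/546/683/1734 px with IQRs [221–314], [468–627], [524–858],
[1032–3152]); with ≥ 200 instances per class the empirical medians land
within 10% of the targets. Shapes are discs, random-orientation ellipses
(axis ratio 1–1.6, the default), or star-convex irregular blobs (radial
polygon with smoothed per-vertex noise) rasterized on the pixel grid with
one rescale pass so the rasterized area tracks the drawn area. Instances
are placed uniformly at random, largest first, with a minimum gap
(default 2 px) enforced through a dilated occupancy footprint.

`degrade()` turns a ground truth into a controlled "prediction":
independent per-instance dropout, spurious background blobs (drawn from
the smallest class's area distribution — the worst case for IoU matching),
fixed erosion/dilation depths, iterated erosion to a target area-loss
fraction (how "~30% removed area" is realized), morphological boundary
jitter plus translation, and class flips. Every change is logged, so tests
can recover the rates they injected (dropout via centroid-match recall,
misclassification via the off-diagonal mass of the matched confusion
submatrix).

The generator does **not** emulate: nucleus texture or staining, spatially
correlated annotation errors, touching/overlapping nuclei (instances are
disjoint by construction), class-dependent spatial clustering, or the
annotation inconsistencies of real datasets. Passing tests therefore show
that the *metrics* behave as analysed under realistic size/shape/error
statistics — not that any segmentation model performs at a given level on
real tissue.

## Numerical and design choices

* Matching ties (equal IoU or distance) break by ascending (gt ID,
  pred ID); all matchers return one-to-one pairings by greedy assignment —
  the described procedures are greedy, so no Hungarian solver is used.
* IoU of two empty masks is an error, not a convention: callers filter
  empty instances (the ambiguous-region mask-out drops emptied instances
  before matching, and perturbation records flag `emptied`).
* Instance maps are taken verbatim; no connected-components relabelling
  (a fragmented instance stays one instance, preserving annotator intent).
* Degraded masks that collide keep the earlier-painted pixel, so
  prediction maps stay single-valued; with the default 2 px gap collisions
  are rare.
* AUROC is not offered: label maps carry no per-class scores. Balanced
  accuracy is the classification metric.
* The inter-rater regression is OLS of $\log_{10}(HD)$ on IoU over matched
  pairs with $HD > 0$ (zero-HD pairs are excluded and counted); which
  variable is log-transformed is a convention, fixed and reported.

## Problem sizes

The shipped analyses use: 4 scenes × 500 instances (1400² px) for the
population and perturbation studies; 2 scenes × 250 instances with 3
raters for the inter-rater study; one 800-instance two-class scene (1500²
px) for the error tradeoff, mirroring the ~861-nucleus patch such
illustrations are built on; and 300-instance scenes for the penalty study.
All are regenerable bit-identically from the seeds in `analysis/`.

## Known limitations

* Only 2D label maps; no 95th-percentile/average HD variants.
* The exact morphology kernel behind published perturbation medians is not
  documented upstream; with the cross kernel on near-elliptical synthetic
  nuclei the medians come out within a few hundredths of the published
  ones, but this is a consistency observation, not a reproduction of the
  original data.
* `read_mask_dir()`/`read_polygon_csv()` are adapters for external dataset
  layouts and are exercised on synthetic fixtures only.
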