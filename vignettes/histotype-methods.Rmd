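---
title: "Methods: protein-based subtyping and weakly supervised slide classification"
author: "histotype"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: protein-based subtyping and weakly supervised slide classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(histotype)
```

This vignette documents the models, parameter choices and numerical
decisions behind `histotype`, and what the synthetic test bed does and does
not establish about real data.

## Protein-based subtyping

A patient's expression of each of the six urothelial differentiation
markers (basal: CD44, CK5, CK14; luminal: CK20, FOXA1, GATA3) is the
median H-score over the patient's tissue-microarray cores. The median is
robust to the loss or damage of individual 1 mm cores, which is routine in
TMA material; `aggregate_cores()` therefore accepts any positive number of
cores per patient and errors only when a patient has no measurement at all
for some marker, because imputing a missing marker would silently distort
the clustering space.

H-scores are standardized per marker (z-scores with the sample SD) so that
markers with compressed dynamic range contribute as much as strongly
bimodal ones. A zero-variance marker is a hard error: a column of
constants carries no subtype information and makes the z-score undefined.

Clustering is agglomerative with **Ward linkage on Euclidean distance**
(`hclust(method = "ward.D2")`). The linkage was a genuinely open choice;
Ward was selected because it favors compact, spherical clusters, which
matches the block structure expected from a marker panel whose two halves
are anti-correlated, and because it has no tuning parameter. The linkage
and distance are recorded in the model object and its JSON sidecar so
downstream users can audit the choice.

Cluster naming does not rely on inspection. With $L(c)$ and $B(c)$ the
mean z-scores of the luminal and basal panels in cluster $c$, the cluster
maximizing $L-B$ is luminal and the cluster maximizing $B-L$ is basal;
with $k=3$ the remaining cluster is *indifferent* (weak expression of both
panels). Ties in `which.max` resolve to the lower cluster index, making
the rule deterministic; the pathological case where one cluster maximizes
both contrasts aborts with a request for manual review rather than
guessing. `k` is a parameter (2 or 3): subtype discovery uses 3, while
classifier training restricts attention to the two distinctive subtypes.

## Slide preprocessing

Tumor annotations are QuPath-style GeoJSON polygons in level-0 pixel
coordinates (0-based, y down). Polygon geometry (shoelace areas,
Sutherland–Hodgman rectangle clipping, even-odd scanline rasterization) is
implemented in the package and cross-checked in the tests against
supersampled per-pixel rasterization.

Tessellation lays a **512 px** grid anchored at the slide origin — not at
the annotation bounding box — so that re-annotating a slide never shifts
tile identities. A tile is retained when the annotated fraction of its
area is at least `min_tumor_fraction` (default 0.5, inclusive, with a
1e-9 tolerance so exact boundary cases are stable in floating point).

Quality control is a pure function of the tile pixels with two rules
applied in order: *background* when more than `max_bg_fraction` (0.5) of
pixels are bright and colorless (HSV saturation < 0.08 and value > 220 on
the 8-bit scale), and *blur* when the variance of the grayscale Laplacian
falls below 15 (8-bit units). The thresholds are exposed in
`qc_tile()` and were fixed once against the synthetic fixtures (uniform
white, defocused patches, textured tissue); they are not claimed to be
optimal for any particular scanner.

Stain normalization is the Macenko method: optical density
$OD = -\log_{10}((I+1)/256)$ per channel, pixels with $\|OD\| \le 0.15$
discarded as background, stain plane from the top two right singular
vectors of the tissue OD cloud, stain vectors at the 1st/99th percentile
of the in-plane angle, hematoxylin identified as the vector with the
larger blue-channel OD, concentrations by non-negative least-squares
projection, and reference maxima at the 99th concentration percentile.
All slides are mapped to one fixed target profile (the canonical H&E OD
vectors H = (0.65, 0.70, 0.29), E = (0.07, 0.99, 0.11), unit-normalized)
— standard, parameter-light and deterministic. Requiring at least 100
tissue pixels guards the SVD against empty tiles. Magnification
harmonization across scanners is deliberately out of scope: tiles are read
at level-0 resolution.

## Weak supervision and cross-validation

Each tile inherits its slide's protein-based subtype as training label;
no tile-level truth exists. Generalization is estimated by repeated
K-fold cross-validation **split at patient level** (default 3 × 3), so no
patient contributes tiles to both sides of any split. The split is plain
random by default, per-repetition seeded and bit-reproducible from
(patient set, seed) regardless of manifest row order; a stratification
flag exists because with few patients per class a random split can leave a
training fold without one class entirely — in that case the plan errors
and the user re-seeds or stratifies. The built-in experiment wrapper
(`run_cv_experiment()`) stratifies, a documented choice for its small
24-slide cohorts. Training folds are class-balanced by downsampling each
class, without replacement, to the minority tile count; validation folds
are never touched.

The tile classifier's backbone is an abstraction mapping tile batches to
two-class probabilities. The package ships `"tiny"`: tiles are
average-pooled to 64 px, pooled again to a 16 × 16 × 3 grid, standardized
with training-set moments, and classified by a one-hidden-layer (width
32, tanh) softmax network trained by minibatch SGD on cross-entropy
(default: 4 epochs, batch 32, learning rate 0.05). All randomness —
initialization and batch order — derives from the config seed; identical
inputs give identical models, and evaluation is a pure function. Optional
augmentation expands the pooled features with the 8 dihedral transforms
(histology has no canonical orientation); it is off by default. Larger
externally trained backbones (e.g. residual networks behind the same
predict surface) are out of scope for this package's test bed, which is
deliberately CPU-sized.

## Slide-level inference

$p^{WSI}$ is the arithmetic mean of the tile probabilities; the label is
the argmax. Confidence bands partition $[0.5, 1]$: *high* $\ge 0.7$,
*low* $\le 0.6$ (the winning score lies within $[0.4, 0.6]$),
*intermediate* in the open gap $(0.6, 0.7)$ — the gap is reported
explicitly rather than silently dropped. An exact 0.5/0.5 tie is defined
(luminal, low, flagged) instead of being left to floating-point chance.
For external cohorts, `ensemble_predict()` averages the slide-level means
of the three fold-models of the best repetition and bands the average;
any other model count must be opted into.

Heterogeneity detection operationalizes "distinguishable clusters of
luminal and basal tiles": tiles whose winning probability reaches
`prob_floor` (0.6) are class-assigned, 4-connected components are computed
per class on the tile grid, and a slide is a candidate when **both**
classes own a component covering at least `min_component_fraction` (0.2)
of all retained tiles. Both parameters are exposed; the defaults mark a
clean 50/50 split as a candidate and salt-and-pepper noise as not.

## Evaluation statistics

AUROC is computed in the Mann–Whitney pair form with midrank ties and the
basal subtype as positive class; precision/recall/F1 follow the same
convention (macro averages available by flag, and both are reported since
per-class versus macro is ambiguous in small published tables). Fold
metrics are summarized as mean ± $t_{0.975,K-1}\, s/\sqrt{K}$; for $K=3$
the multiplier is 4.30265, which is why three-fold intervals are wide.
Confusion matrices concatenate all validation folds of a repetition, and
a slide predicted twice is treated as split leakage and aborts.

`fisher_exact_2x2()` enumerates the hypergeometric support directly; the
two-sided p-value sums probabilities no larger than the observed table's
(1e-12 slack for floating-point ties). The one-sided alternatives sum the
corresponding tail of the top-left cell — note that for the symmetric
modal table [[1,1],[1,1]] this gives 5/6, not 1; only the two-sided value
is 1. Rank comparisons wrap the standard R tests (`wilcox.test`,
`kruskal.test`): exact enumeration up to n = 25 without ties, normal
approximation with continuity correction otherwise (R cannot enumerate
exactly under ties; the approximation is documented rather than hidden).
Raw p-values are reported without multiplicity correction, matching how
such association panels are usually published.

## The synthetic test bed

`gen_hscore_cohort()` plants three latent subtypes: a patient's own panel
is drawn at N(220, 40), the opposite panel at N(20, 15), indifferent
patients at N(15, 10) on all markers; four cores per patient add N(0, 15)
noise and everything is truncated to [0, 300]. These effect sizes emulate
a strongly bimodal IHC panel; at the defaults the subtyper recovers
essentially all planted labels, which validates the machinery, not the
clinical separability of real cohorts.

`gen_pseudo_slide()` renders textures in **stain-concentration space**:
every pixel gets hematoxylin/eosin concentrations (dense nuclear ellipses
at high H for luminal; oriented stromal fibers and sparse bright keratin
blobs at high E for basal; concentration noise SD 0.015) and is converted
once through the Beer–Lambert model with the canonical H&E vectors. This
guarantees the fixtures live in a true two-stain subspace — so Macenko
estimation and normalization behave as on idealized tissue — and gives the
luminal texture ≥ 0.1 more mean blue-channel OD, making the two classes
separable from color alone. That is intentional: the end-to-end test is
about the pipeline (splitting, balancing, aggregation, banding), not about
texture learning. Consequently a perfect synthetic AUROC says nothing
about real-cohort AUROC, which requires real slides and a trained deep
backbone. Artifacts (white margins, a blurred tile-aligned patch) exercise
QC; per-slide seeds are derived from (master seed, slide index) so cohorts
are stable under count changes.

## Problem sizes

The test suite and the acceptance script run the full experiment at
24 slides of 3072 × 2048 px (24 candidate tiles each, 576 tiles total),
3-fold single-repetition CV with the tiny backbone — about five minutes on
one CPU — plus oracle suites (1000 AUROC instances, 200 Fisher tables, 20
random polygons, 50 random 20 × 20 maps), 20 subtyping seeds of 90
patients, and 200 independence replicates at n = 24 for the empirical size
of the Fisher test. These sizes were chosen as the smallest at which every
mechanism is exercised with comfortable statistical margin.

## Known limitations

- No automatic tumor segmentation: annotations are required inputs.
- No magnification/resolution harmonization across scanners.
- The shipped backbone is a small pooled-pixel MLP; it separates the
  synthetic textures but is not a histology feature extractor.
- Heterogeneity detection is connected components on the tile grid — no
  spatial statistics beyond that.
- No survival analysis and no multiple-testing machinery, by design.
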