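---
title: "From keypoints to maternal behavior: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From keypoints to maternal behavior: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nestwatch)
```

## The problem

Rodent dam-pup interactions (nest attendance, nursing postures, licking and
grooming, and the dam's own maintenance behaviors) are classically scored by
hand from home-cage video, which is slow, coarse, and hard to standardize.
`nestwatch` implements the post-pose-estimation half of an automated
alternative: it starts where a pose estimator ends — per-frame keypoint
coordinates with detection likelihoods for the dam (32 points) and for the
pups of a litter (9 points per detected pup, identity-free) — and ends with
frame-level annotations of seven behaviors, bout tables, per-video summary
measures, and explainability reports. It never touches video pixels and does
not train pose networks.

The seven behaviors are `r paste(behavior_vocabulary(), collapse = ", ")`.
They are scored by seven *independent* binary classifiers: no mutual
exclusivity is enforced, because co-occurrence is real (nursing implies nest
attendance by definition).

## Data model and I/O

Three kinds of input meet in one flat per-frame table:

* **Dam pose**: a single-animal pose CSV in the three-row-header dialect
  (`scorer` / `bodyparts` / `coords`, then `x, y, likelihood` per keypoint).
  Likelihoods outside $[0,1]$ are clipped, not rejected — upstream float
  noise should not kill a run.
* **Pup detections**: the *mid-workflow* output of a multi-animal tracker —
  per frame and per bodypart, a variable-length list of `(x, y, confidence)`
  with no pup identity. Identity maintenance (tracklet stitching) is
  deliberately abandoned: in a huddle most pups are partially occluded and
  assembled tracks lose most detections, while the pipeline only needs the
  litter as a collective. Two interchangeable on-disk dialects are read and
  written: a portable JSON document and a long CSV
  (`frame, bodypart, x, y, confidence`). The tracker's own serialized
  (pickle) detections file is not parsed here; convert it to either dialect
  first.
* **Annotations**: BORIS-style interval exports (`behavior, start, stop` in
  seconds), rasterized with the half-open rule — frame $f$ is positive iff
  $\text{start} \le f/\text{fps} < \text{stop}$ — so adjacent bouts never
  double-count a boundary frame.

`detections_to_table()` assigns detections to fixed pup *slots* per frame
and bodypart in descending confidence order (ties: ascending x, then y), up
to `max_pups` (default 12, a fixed schema width that covers typical
Long-Evans litters); unfilled slots carry `(0, 0, p = 0)`. Slot numbers
carry **no** identity across frames, which is why every downstream feature
is a symmetric function of the slots (verified by a slot-permutation
invariance test). When dam and pup tables disagree in length the join
truncates to the shorter side — padding would fabricate detections.

Calibration is one scalar, `px_per_mm`, measured from a structure of known
physical size (by convention the wire cage-top width at its lowest point).
In a side view the true scale varies with depth; the single scalar is a
deliberate compromise that removes between-recording differences in camera
distance and resolution.

### Keypoint rosters

The exact 32-name dam roster and 9-name pup roster are versioned package
constants (`keypoint_scheme()`). Downstream code references named *groups*
(ordered `back_points` for the arch angle, `ear_points`, head, ventrum,
limb, flank, tail), never raw indices, so the roster can evolve without
touching feature code.

## The 218-feature matrix

`extract_features()` computes 218 features per frame, fixed in a versioned
manifest (`feature_manifest()`): eight categories — dam location, dam
areas, dam angles, dam probabilities, dam movement, pup area, pup
probabilities, dam-pup distances — derived from dam data only (172),
pup data only (19) or both (27). Because occlusion is pervasive and no
outlier-correction pass is applied, every calculation handles low-likelihood
points explicitly, in one of two documented ways:

* **probability weighting**: centroids are
  $\left(\sum_i p_i x_i / \sum_i p_i,\; \sum_i p_i y_i / \sum_i p_i\right)$,
  and per-keypoint movement is the frame-to-frame displacement scaled by
  $\min(p_t, p_{t-1})$;
* **threshold exclusion**: hulls and circle fits use only points with
  $p \ge p_{\min}$ (default $0.5$, matching the likelihood cutoff used when
  the pose models were evaluated).

Degenerate geometry never emits NaN, because the downstream tree models
cannot ingest it: hull areas with fewer than three admissible points are 0,
collinear circle fits are 0 (a flat back genuinely has no arch), and
undefined centroids hold the last defined value (leading gaps take the
first defined value; a track that is never defined falls back to the cage
centre and is flagged low-confidence).

The **back-arch angle** — the posture proxy that separates arched (active)
nursing from flat postures — is the central angle at a circle fitted through
the admissible back points (algebraic least-squares, Kåsa), subtended
between the first and last admissible points, taking the arc through the
interior points; a fit whose radius exceeds 100 chord lengths is treated as
collinear. On noise-free points from a known circle the analytic angle is
recovered to $10^{-6}$ degrees (tested).

Rolling windows are **trailing (causal)**: a window of
$w = \max(1, \mathrm{round}(\text{span} \times \text{fps}))$ frames ends at
the current frame, shrinking at the start of the video; the standard
deviation of a single-frame window is 0. Causality keeps single-pass
streaming possible; alignment is otherwise a free choice and is simply
documented. Spans are 0.1 s, 1 s and 2 s with mean/sum/std. Two long
windows (30 and 60 minutes) smooth the *pup centroid* for some dam-pup
distance features, bridging stretches where the litter is fully occluded
by bedding or the dam. One deliberate deviation inside the dam-location
category: rolling *sums* of raw coordinates are not used (a trailing sum of
a coordinate scales with window length, which would break the documented
behavior that location features shift by exactly a rigid translation);
location windows use mean and std only, and the counts are balanced across
categories accordingly.

Units: locations in frame px; distances, movement in mm; areas in mm²;
angles in degrees; probabilities unitless. Invariances asserted by tests:
pup-slot permutation invariance; rigid translation moves location features
by exactly the translation and nothing else; doubling `px_per_mm` halves mm
features, quarters mm² features, and fixes angles and probabilities.

## Classifiers

One binary random forest per behavior (`train_classifier()`):

* every-other-frame thinning per video (adjacent frames are nearly
  duplicates), then a **stratified** 80/20 train/test split at a fixed
  seed — stratification matters because the rarest behavior runs at a few
  percent prevalence;
* forest settings: `n_trees` in $[100, 1500]$ (default 500 — mid-range,
  recorded in the bundle), minimum leaf 1 or 2, $\sqrt{p}$ features per
  split, no sampling adjustment. The forest is fitted as a single round of
  parallel trees with unshrunken leaf means on 0/1 labels, so each tree
  predicts a leaf label mean and the forest prediction is a probability;
  variance-reduction splitting on 0/1 targets is equivalent to gini
  impurity splitting, so the classical criterion is preserved;
* the **discrimination threshold** is chosen from the precision-recall
  curve on the test split: smallest threshold attaining maximal F1. The
  visual-inspection adjustment used in manual workflows becomes an explicit
  `threshold_override`, recorded with provenance `"manual"`. Probability
  exactly at threshold is positive (`>=`).

`evaluate()` reports precision, recall and F1, with zero-denominator cases
flagged and scored 0. `merge_behaviors()` ORs two label vectors, the
standard remedy when two classes (eating and drinking) trade false
positives. Determinism: identical features, labels, hyperparameters and
seed give bit-identical bundles and predictions (single-threaded forest,
seeded split).

## Bouts and summaries

A bout is a maximal run of positive frames — a single frame suffices.
Spans are inclusive with $\text{duration} = (\text{end} - \text{start} +
1)/\text{fps}$, making label vectors and bout tables a bijection (tested).
Minimum-bout smoothing (`smooth_min_bout()`) drops short bouts without
merging across gaps and is off by default, because headline duration
numbers should be computed raw; gap merging exists but is likewise off.
`summarize_video()` reports total duration, percent time, bout count and
mean bout duration per behavior; `cohort_table()` exports a long-format
table (video × behavior with litter/day metadata) for external statistics
packages — the mixed-model analysis itself is out of scope.

## Explainability

`permutation_importance()` shuffles one feature column at a time
(`n_repeats` shuffles, seeded; default 5 — the convergence property is
tested at 20 on a toy fixture) and scores the mean drop in F1 at the
bundle's threshold. Features are ranked 1 (most important) to 218; exact
ties break by manifest order. `category_mean_rank()` averages ranks within
the eight categories. Note the rank range is 1..218 because 218 features
exist; documents that quote 217 for the same construction are
off-by-one.

`attribution_sample()` draws 150 behavior-present and 150 behavior-absent
frames (all available, with a warning, when fewer exist) and computes
additive per-feature attributions with the forest's exact tree-path
attribution backend (TreeSHAP, provided by the forest library — the
algorithm itself is not reimplemented here). Because the forest is fitted
without subsampling, the attribution bias term equals the training positive
fraction exactly, so for every frame
$\text{base rate} + \sum_j \phi_j = \hat{p}$ within $10^{-6}$ (tested).
`attribution_category_sums()` sums mean attributions per category,
separately over present and absent frames, preserving sign.

## The simulator

`simulate_session()` generates fully in-silico sessions so that every stage
is testable without data downloads. It is a **test oracle, not a
biomechanical model**: behavior templates are parametric and deliberately
simple, chosen so that the feature families the pipeline computes are what
separates the classes — zone occupancy (nest / food hopper / water spout),
back-arch curvature (~150° arched for active nursing, ~60° neutral, ~6°
flat for passive nursing), 6 Hz nose/ear oscillation for licking/grooming
(near the pups) and self-grooming (away from them), an upward head angle
for drinking, and a laterally stretched low-movement template for passive
nursing. Pups cluster in the nest with per-keypoint detection dropout
(default 0.5 in-nest — in-nest pups are heavily occluded — and 0.1
off-nest); dropped dam keypoints come back as *garbage coordinates with
p = 0*, exactly the failure mode probability weighting must absorb.
Defaults mirror the recording conditions the pipeline targets: 30 fps,
1280×780 px, ~2.28 px/mm, 8 pups, 4 px coordinate jitter, 15% dam keypoint
dropout.

Scripts are semi-Markov timelines covering all states, with 1.5 s
*unlabeled* transit gaps between segments, as a human annotator leaves
locomotion between behaviors unscored; ground truth equals the script
rasterized at fps. All randomness flows from one scenario seed through
named substreams (script, dam motion, dam pose, occlusion, pups), so
sessions are bit-identical under a fixed seed.

What passing tests on simulated data do and do not show: they verify that
the feature engine preserves the geometric information the classifiers
need, that the training/thresholding/evaluation machinery recovers scripted
structure from noisy, occluded keypoints, and that performance degrades
monotonically as occlusion rises. They do not certify performance on real
videos — real postures, lighting, nest-building and pose-estimator error
structure are richer than the templates — so classifier quality on real
recordings must still be judged on annotated held-out videos.

## Problem sizes and numerical choices

Test and acceptance runs use 40-60 s sessions at 30 fps (1200-1800 frames):
20 training + 4 held-out sessions for the recovery suite and 12 + 3 for
the acceptance script, with 100-150 trees — sizes chosen so the full suite
exercises every code path at desk scale while the statistical margins stay
wide (held-out F1 thresholds 0.95 for nest attendance, 0.85 for all
behaviors). Other fixed numerical choices: the Kåsa fit declares
collinearity at determinant ratio $10^{-10}$ or radius > 100 chords;
rolling std uses the $n-1$ denominator with single-frame windows defined
as 0; probability clipping (not rejection) for stray likelihoods; slot
ties broken by ascending x then y.

## Known limitations

* The feature roster honors all documented constraints (218 features,
  172/19/27 source split, eight categories, window spans, long-window pup
  centroids) but its exact membership is this package's own versioned
  choice; bundles record the manifest version and refuse mismatched
  feature tables.
* The single `px_per_mm` scalar ignores depth-dependent scale in side
  views; mm-denominated features are comparable between recordings, not
  exact physical measurements.
* No pickle ingestion for the tracker's native detections file; use the
  JSON or CSV dialect.
* The simulator's occlusion model is i.i.d. per keypoint; real occlusion
  is temporally correlated.
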