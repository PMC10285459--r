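---
title: "Rotated-box detection of slender crop-damage symptoms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rotated-box detection of slender crop-damage symptoms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rotodet)
```

## The problem

Rice leaffolder (*Cnaphalocrocis medinalis*) larvae roll rice leaves and
feed inside them, leaving pale elongated scars on the canopy. Survey work
estimates infestation pressure by counting these damage symptoms in field
photographs. The symptoms are long, thin, and oriented every which way
with the leaves, and they frequently cross one another. An axis-aligned
bounding box around such a scar is mostly background, and one axis-aligned
box often swallows several crossing scars, so horizontal detectors both
localize poorly and confuse the features they pool. The natural object
representation is a *rotated* bounding box, and the natural detector is a
two-stage network whose second stage pools features aligned with the
rotated candidate region.

`rotodet` implements that pipeline end to end in R: the rotated-box
geometry, annotation I/O for the roLabelImg and labelImg XML dialects, a
synthetic scene generator with the statistical structure of field imagery,
pyramid anchors with adaptive positive-sample selection, delta box coding
and losses, rotated region-of-interest alignment, a compact trainable
two-stage detector, and oriented average-precision evaluation.

## Box convention

A rotated box is `(x, y, w, h, theta)`: center in continuous image
coordinates (origin top-left, y down), `w` the **long** edge, `h` the
short edge, and `theta` the clockwise rotation of the long edge from the
x-axis. Because a rectangle is symmetric under half-turns, `theta` lives
on a circle of period `pi`; the canonical range is `[-pi/4, 3*pi/4)`.
`rbox()` enforces this *long-edge convention*: any `(w, h, theta)` triple
is swapped/wrapped into the single canonical representation at
construction, so all downstream code can assume `w >= h` and a canonical
angle. Boxes with an edge below `1e-6` px are rejected at construction;
the detector therefore never emits degenerate zero-area boxes.

## Geometry: skew IoU, IoF, and rotated NMS

The overlap of two rotated rectangles is the area of their convex
intersection polygon. We compute it by Sutherland–Hodgman clipping of one
quadrilateral against the other followed by the shoelace formula, which is
algebraically identical to dissecting the intersection polygon into
triangles at its vertices. Two derived ratios matter:

* **skew IoU** — intersection over union, the symmetric matching measure;
* **skew IoF** — intersection over the *detection's* area. Field symptoms
  are often truncated at the image border or interrupted; a detection
  covering a real fragment of a larger annotated scar has a low IoU but a
  high IoF, so evaluation under IoF is the forgiving companion metric.

Numerical policy: collinearity tolerance `1e-9` in the clipper; boxes that
merely share an edge or vertex have intersection area 0 (and IoU 0), which
avoids sign-noise branches in degenerate contact. Rotated non-maximum
suppression is the standard greedy sweep in descending score order under
skew IoU, with score ties broken by ascending input index so results are
deterministic. These kernels are written in C++ (via Rcpp) because NMS
over a few thousand proposals performs on the order of a million polygon
clips; the test suite cross-checks the clipping against an independent
Monte-Carlo rasterization oracle.

## Annotations

The roLabelImg dialect stores `cx, cy, w, h, angle` per instance. We store
the angle in radians in `[0, pi)` for the *stored* `w` edge and
canonicalize on read, so any aliased representation in a file maps to the
same in-memory box; writing uses the same mapping, making write–read round
trips lossless to `1e-6`. Horizontal datasets are derived by replacing
each rotated instance with its circumscribed axis-aligned rectangle
(labelImg `xmin/ymin/xmax/ymax`); boxes are *not* clipped to the image by
default, because circumscription of a truncated symptom may legitimately
extend past the frame (a `clip` flag exists). Datasets are summarized by
instance counts (images with 1–9 instances are "sparse", 10–19 "medium",
20+ "dense"), an aspect-ratio histogram over bins
`[1,2), [2,3), [3,5), [5,8), [8,Inf)`, and an 8-bin angle histogram over
the canonical range; the exact binning of the field data's published
distribution plots is not recorded anywhere, so these bins are our choice.

## The synthetic field generator

Real field imagery for this task is not redistributable, so the package
ships a generator that emulates its *statistical* structure rather than
its radiometry: a textured green canopy (two octaves of smooth value
noise plus pixel noise), pale yellow-white streaks rendered inside their
ground-truth rotated boxes with alpha falloff toward the box edges, and
optional "sunlight" scenes with a linear brightness ramp (up to +40%) and
specular blobs. The samplers mirror the reported dataset structure:

* per-image counts drawn uniformly from 1–9, 10–19 or 20–35 according to
  the named density class;
* orientations uniform over `[-pi/4, 3*pi/4)`;
* aspect ratios from a mixture with probability 0.55 of the slender range
  (5, 10) and otherwise (1.5, 5), matching the reported "more than half
  above 5";
* long edges uniform in 30–110 px at the default 256 px scene size, and
  a crossing probability (default 0.25) that plants an instance next to
  an earlier one so streaks overlap and cross.

Everything is a deterministic function of `(spec, seed)`; datasets
written to disk reproduce byte for byte. What the generator does *not*
model — occlusion by leaves, curved scars, real canopy texture — bounds
what the tests can show: a detector that works here has the geometric
machinery right, but no claim is made about accuracy on real imagery.

## Anchors and adaptive sample selection

The proposal stage places three horizontal anchors (aspect ratios 2, 1,
0.5 before canonicalization) at every position of pyramid levels with
strides 4–64 and areas `32^2`–`512^2`. A fixed skew-IoU threshold cannot
define positives for slender rotated targets: even a perfectly placed
horizontal anchor has a structurally low skew IoU with a thin oblique
box. The assignment is therefore adaptive per instance: gather the 9
center-closest anchors per level, compute their skew IoUs with the
instance, and set the threshold to `mean + population sd` of that
candidate set. Instances whose candidates all fall below their threshold
receive their best candidate as a forced positive, and an anchor wanted
by several instances goes to the one it overlaps most (if that strips an
instance of its last positive, it is repaired from still-unlabeled
candidates) — so *every* instance owns at least one positive anchor, a
guarantee the test suite checks on generated scenes. Training batches
take up to 256 anchors per image at a strict 1:1 positive:negative
ratio; when positives are scarce the batch shrinks rather than padding
with negatives, and the loss normalizes by the realized batch size.

## Coding and losses

Boxes are regressed as deltas against their anchor (or proposal): center
offsets normalized by the anchor edges, log edge ratios, and the raw
angle difference. Decoding inverts the coder, wraps the angle back into
`[-pi/4, 3*pi/4)`, and canonicalizes. The raw angle difference is kept as
the default; an optional `wrap_angle` toggle re-expresses differences
beyond `pi/2` through the angle period, shortening the regression path
across the angular boundary, but it is off by default to keep the
reference behavior. The loss is cross-entropy over all sampled anchors
plus smooth-L1 over the five delta components of the positives, with a
single shared `1/N` normalization across both sums — note this differs
from frameworks that normalize the regression term by the positive count
alone. The proposal head scores objectness with a sigmoid; the
refinement head classifies with a 2-way softmax.

## Rotated RoI alignment

A proposal is projected to the feature frame by dividing its edges by the
stride and *flooring* its center coordinates; the floor introduces up to
half a cell of quantization and is kept as the reference behavior (a
`floor_center = FALSE` toggle exists for ablation). The proposal's
interior is split into `k x k` bins in its local frame (first grid axis
along the long edge; `k = 7` by default), each bin is sampled at `l = 4`
sub-bin centers (a 2x2 grid; `l` must be a perfect square), each sample
is rotated into the feature map and read by bilinear interpolation with
zero padding outside the map, and samples average per bin. Pooling is
exactly linear in the feature map, reproduces constants exactly, and
reduces to axis-aligned RoIAlign at `theta = 0` — all tested invariants.

## The detector

Two backbones share one interface: `"resnet50"` — the full-scale
bottleneck architecture with an FPN neck (256 channels), the proposal
head, and a refinement head with two 1024-wide fully-connected layers —
and `"tiny"`, a 4-stage CNN (16–128 channels, 64-channel neck, 128-wide
head) that exists so end-to-end training and inference run in seconds on
a CPU. The full-scale graph carries 41.38 M trainable parameters
(convolution biases included; implementations that run convolutions
bias-free under batch normalization report ~41.1 M). Proposals are
decoded per level, capped at the top 2000 by score (600 for the tiny
preset), filtered by rotated NMS at 0.8, aggregated across levels and
capped again (2000 training / 1000 inference; 300/100 tiny). Each kept
proposal pools a `k x k` rotated-aligned region from the pyramid level
matching its size (`clamp(floor(log2(sqrt(w h) / 56)) + 2, 2..5)`),
passes the two fully-connected layers, and emits a softmax foreground
probability and a 5-delta refinement decoded against the proposal.
Detections below a 0.05 score threshold are dropped and the survivors
pass rotated NMS at 0.1; these inference thresholds are conventional
two-stage defaults and are all configurable.

## The demo trainer

`train_demo()` runs SGD with momentum 0.9, batch size one image, step
learning-rate decay (×0.1) at 2/3 and 11/12 of the run, and a global
gradient-norm clip of 10. All gradients are assembled by hand, layer by
layer, and verified against central finite differences in development;
proposals are treated as constants in the refinement stage (gradients
flow to the features through the pooling, not to proposal coordinates),
the standard two-stage approximation. Ground-truth boxes are appended to
the training proposals so the refinement head sees positives from the
first iteration. Refinement-stage samples are capped at 64 per image at
1:3 positive:negative (a demo-scale reduction of the conventional
512-sample configuration, chosen to keep a 200-iteration run around
three minutes on one CPU core; the cap is a `train_demo` argument). The
default learning rate is 0.01, the largest value that trained stably
across the demo grid we tried (0.05 diverged, 0.005–0.01 plateaued
similarly). The demo problem size — 50 training scenes and 20 held-out
scenes of 128 px, 200 iterations — is deliberately small; it
demonstrates that the full pipeline learns (held-out rotated AP rises
strictly above the untrained baseline) and nothing more.

## Evaluation

Detections are matched per image in descending score; a detection is a
true positive if its best-overlap not-yet-matched ground truth meets the
threshold under the chosen criterion (skew IoU or skew IoF), ties going
to the lower ground-truth index. Precision–recall points are swept over
every distinct score and AP is the area under the precision envelope as
a function of recall (all-points interpolation; the classic 11-point
variant is available). Two caveats worth knowing: greedy matching is not
globally optimal, so with heavily shared ground truths the strict
orderings "AP at 0.5 >= AP at 0.75" and "IoF-AP >= IoU-AP" can be
violated by re-pairings even though they hold pairwise; they are exact
whenever each detection contends for a single ground truth, which is how
the property tests are constructed.

## Worked example

```{r example, eval = FALSE}
dir <- file.path(tempdir(), "demo")
generate_dataset(scene_spec(density = "sparse"), 5, dir, seed = 1)
summary <- dataset_summary(read_annotation_dir(dir))
summary

model <- build_model(detector_config("tiny"), seed = 0)
trained <- train_demo(dir, model, iterations = 50)
dets <- detect(file.path(dir, "img_0001.png"), trained$model)
dets
```

## Known limitations

* The trainer is demo-scale by design: single-image batches, a tiny
  backbone, no weight decay, no augmentation, no pretrained weights.
* Masks, polygonal lesions and curved symptoms are out of scope; the
  rotated rectangle is the finest shape modeled.
* The synthetic generator's radiometry is a stand-in; its sunlight mode
  in particular is a simple ramp-plus-glare model labeled as such.
* Single-class evaluation only; no COCO-style threshold averaging.
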