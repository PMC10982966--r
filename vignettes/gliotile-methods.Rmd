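---
title: "Tile-level semi-supervised glioma subtype classification: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tile-level semi-supervised glioma subtype classification: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(gliotile)
```

## The problem

Digital pathology classifies gigapixel whole-slide images (WSIs) of H&E-stained
tissue in fixed-size tiles, because no model ingests a 100,000 x 100,000-pixel
scan whole. For adult-type diffuse gliomas the clinically relevant tile classes
are the three WHO 2021 subtypes -- IDH-mutant astrocytoma (`ac`), IDH-mutant
1p/19q-codeleted oligodendroglioma (`odg`), IDH-wildtype glioblastoma (`gbm`)
-- plus `normal` brain tissue and `necrosis`. Pathologists annotate a handful
of rectangular regions of interest (ROIs) per slide; everything else on the
slide is unannotated tissue. Annotation is the scarce resource, which makes two
properties of the data exploitable:

1. **Slide-level weak labels.** Every slide carries a diagnosis. A slide
   resected for glioblastoma can contain glioblastoma, normal tissue, or
   necrosis -- but not oligodendroglioma. Any model prediction violating this
   rule is wrong with certainty, for free.
2. **Unannotated tiles are abundant.** The tissue outside the ROIs is the same
   tumor; a model confident about it can teach itself from it.

`gliotile` implements the resulting pipeline: overlapping-tile extraction from
ROIs, dihedral augmentation, per-channel normalization, class-weighted
training with best-epoch selection, one round of confidence- and
diagnosis-gated pseudo-labeling followed by a full retrain, macro-averaged
evaluation, and slide-level probability heatmaps. A seeded synthetic cohort
generator stands in for the clinical WSIs so that the entire procedure is
testable end to end on a laptop.

## Tiling model

ROIs are axis-aligned rectangles with 0-based, half-open pixel coordinates
`[x, x + width) x [y, y + height)`. Each ROI is divided into square tiles of
side $T$ (default 512 px) at stride $S = T(1 - \mathrm{overlap})$ (default
overlap 0.5, so $S = 256$). Partial tiles at edges are dropped -- padding
would fabricate tissue -- giving the closed form

$$ n(\,W, H\,) \;=\; \Big(\big\lfloor (W-T)/S \big\rfloor + 1\Big)\,
                     \Big(\big\lfloor (H-T)/S \big\rfloor + 1\Big) $$

for $W, H \ge T$ and 0 otherwise, which the tests verify against exhaustive
position enumeration. A tile that fits inside two overlapping ROIs of
different classes is an annotation conflict and raises an error rather than
being silently double-labeled.

Training tiles are expanded to their full 8-element dihedral (D4) orbit --
rotations by 0/90/180/270 degrees, with and without a horizontal flip,
identity view included. We read "8 views" as the orbit including the identity:
the orbit is then exactly the symmetry group of the square, closed under
composition, and multiplies training counts by exactly 8. Test tiles are never
augmented; the API enforces this with an error rather than a convention.

Channel normalization subtracts the per-channel mean and divides by the
per-channel standard deviation pooled over all training-tile pixels
(population form, floored at $10^{-6}$). The statistics come from the
training split only and are reused verbatim at test time -- computing them on
"the dataset" without specifying the split invites test leakage, so the
conservative reading is baked in.

A tissue filter (retain tiles whose fraction of pixels darker than an
intensity cutoff is at least a threshold, inclusive comparison) is provided
for slides with blank background. Its own default threshold is 0.05, but the
pipeline does not apply it unless configured: the synthetic slides are fully
tissue-covered, and on clinical slides the choice belongs to the operator.

## Classifier

The class imbalance is severe -- in the cohort shape the generator mimics,
normal tissue outnumbers necrosis roughly 18:1 at the tile level -- and is
handled in the loss, not by resampling: categorical cross-entropy weighted by
inverse class frequency,

$$ w_c = \frac{N}{K\,n_c}, \qquad \sum_c n_c\,w_c = N, $$

with $N$ total training tiles, $K$ classes and $n_c$ the count of class $c$.
This normalization (weighted mean 1) keeps the loss scale comparable across
imbalance levels; the conservation identity is asserted exactly in the tests.

The backbone is pluggable through a registry. The package ships a deliberately
small default, `texture_softmax`: 18 per-tile texture features (per-channel
mean and standard deviation plus 2x2 block channel means of the normalized
tile) under a linear softmax head, trained by seeded minibatch SGD (defaults:
10 epochs, batch 32, learning rate 0.5, features standardized on the training
fold). A one-hidden-layer variant (`texture_mlp`, 16 tanh units) is included,
and `register_backbone()` accepts any user featurizer. The design premise is
the same one that makes tile classification work at all: class identity must
be recoverable from local texture. Large pretrained vision backbones slot in
behind the same registry but are intentionally out of scope -- nothing in the
two-step procedure depends on the backbone's capacity, and a small model keeps
every property of the procedure testable in seconds.

Each fit holds out a validation fold of whole slides (about 20% of tiles) so
that no slide contributes to both folds -- tiles from one slide are strongly
correlated, and a tile-level split would overstate validation performance.
The fold is chosen so every class keeps support in the training fold; in
degenerate cohorts where no whole slide can be spared the split falls back to
a stratified per-tile split. After each epoch the validation balanced accuracy
is recorded and the weights of the best epoch are returned. Selecting the best
epoch on the *test* set would leak the test data into model selection, so the
package selects on validation data by design, accepting that this is the
stricter protocol.

## Two-step semi-supervised procedure

Step 1 trains on the augmented ground-truth tiles. The fitted model then
predicts every grid tile of the *training* slides that does not intersect an
ROI. A prediction becomes a pseudo label only if

* its confidence (maximum class probability) is **at least 0.90** -- the
  comparison is inclusive, so exactly 0.90 passes -- and
* the predicted class is permitted by the slide's diagnosis: $\{d,$ normal,
  necrosis$\}$ for tumor diagnosis $d$, and $\{$normal$\}$ for the
  normal control. The tumor rule is the clinical annotation convention; the
  control rule is this package's decision (a non-cancer control with necrosis
  is not represented in the cohorts modeled here), flagged in the
  `class_scheme()` documentation.

Retained tiles are merged with the ground truth (tile identities must be
disjoint; sizes and per-class counts are additive) and a fresh model is
retrained on the merged set from a new seeded initialization. Three choices
here were genuinely open:

* **One round only.** The procedure is described as two-step; iterating
  self-training schedules is out of scope and the round count is not a
  configuration knob.
* **Fresh retrain, not warm start.** "Retrain" is read as a full retrain on
  the merged dataset. A warm start from step-1 weights would couple the two
  steps' optimization trajectories and make the pseudo-label contribution
  harder to attribute.
* **Pseudo tiles are not augmented by default.** Pseudo labels are noisy;
  8-fold augmentation multiplies the noise by 8 while adding no new
  information. A flag (`augment_pseudo`) exists for users who want parity
  with the ground-truth treatment.

Test slides never contribute pseudo labels; the tests assert that the audit
trail's slide set is disjoint from the test split.

## Evaluation

All metrics are computed at the tile level on the held-out test slides.
Balanced accuracy is the macro-average of per-class recall; under macro
averaging it *is* macro recall, and the package computes it once and reports
it under both names. Macro precision/recall/F1 use one-vs-all reductions with
equal class weights; macro-F1 is the mean of per-class F1 values (not the F1
of macro-P and macro-R, which differs). A class never predicted contributes
precision 0 with a warning -- the conservative zero-division convention.
Classes with zero test support are excluded from the averages with a warning.

The binary collapse folds the 5x5 confusion matrix onto the tumor/non-tumor
partition and reports the false-alarm rate (predicted tumor given true
non-tumor) and missed-cancer rate (predicted non-tumor given true tumor);
subtype confusions such as `ac` vs `odg` leave both rates untouched, which is
exactly why the collapse is reported separately.

## Heatmaps

Per-tile probability vectors are projected back onto the slide on a grid of
stride-sized cells. Overlapping tiles are combined by unweighted mean -- the
mean of probability vectors is again a probability vector, so every covered
cell stays on the simplex (asserted in tests); max-pooling is available only
as a visualization flag because it breaks that semantics. Uncovered cells are
`NA`, never zero: "no evidence" and "zero probability" are different
statements. Overlays upscale the grid by nearest neighbor so cell boundaries
remain visible and no interpolation invents confidence between cells.

The slide summary reports, per class, the fraction of covered cells where the
class attains the argmax, and calls the dominant tumor class. When the top
two tumor fractions differ by less than a margin (default 0.1) the call is
flagged *inconclusive* -- a threshold we introduced to operationalize the
qualitative situation where a slide reads ambiguously between the two
IDH-mutant subtypes, and configurable because 0.1 is a reporting convention,
not biology.

## The synthetic cohort

The generator emulates the statistical structure the pipeline relies on, not
histology. Each class is a marked Poisson process: disks of a
hematoxylin-leaning foreground color (expected count = density x area,
uniform centers) over an eosin-leaning background, plus Gaussian noise
(sd 0.02) clipped to [0, 1]. Classes differ in density, radius and both
colors -- glioblastoma is the densest/darkest (hypercellularity), normal
tissue the sparsest, necrosis the pinkest with the largest blobs. A
`difficulty` parameter shrinks all parameters linearly toward their
cross-class mean: at 0 classes are maximally separated, at 1 identical. The
tests verify the endpoints behaviorally: at difficulty 0 a linear
discriminant on per-tile channel means exceeds 90% balanced accuracy; at
difficulty 1 it drops to chance and mean-intensity distributions become
statistically indistinguishable.

The default cohort mimics a small surgical series: a 29-slide diagnosis mix
of 8 `ac` : 8 `odg` : 12 `gbm` : 1 normal control, scaled to `n_slides`, and
per-class tile-share targets of roughly 0.232 / 0.209 / 0.101 / 0.434 / 0.024
(`ac`/`odg`/`gbm`/normal/necrosis) -- severe imbalance with normal:necrosis
about 18:1. A planner apportions integer tile counts (largest-remainder) to
classes within each train/test split, subject to the diagnosis rule, and
packs stride-aligned textured regions into each slide; the realized shares
and their relative deviation from the targets are reported on the cohort
object. Every slide is *fully covered* with tissue (normal texture as canvas,
class regions painted on top), and only a `roi_coverage` fraction of each
region is annotated as an ROI. This is what gives the semi-supervised step
honest work to do: at `roi_coverage = 0.2`, 80% of each tissue region is
unannotated, latently labeled tissue. Annotation scarcity is a training-side
condition: test slides are always fully annotated, so the evaluation ground
truth keeps its size and per-class support.

Randomness uses one root seed with per-slide child streams, so cohorts are
reproducible slide by slide and byte-identical across runs. What the
generator does **not** emulate -- nuclear morphology, stain variation,
scanner artifacts, multi-resolution pyramids, inter-patient heterogeneity --
bounds what passing tests mean: they demonstrate that the *procedure* (tiling
arithmetic, gating logic, bookkeeping, training mechanics, metric
definitions) is correct and that the semi-supervised step helps when its
assumptions hold, not that any particular accuracy transfers to clinical
slides.

## Problem sizes and numerical choices

The shipped test suite and the acceptance script run two cohort scales,
chosen as the smallest sizes at which every class appears in every split and
the semi-supervised step has a meaningful pool of unannotated tiles:

* a fully separable run: 20 slides of 2048 x 2048 px, ~12 ground-truth tiles
  per slide at 512-px/50%-overlap geometry, 10 epochs;
* a harder, partially annotated run: 12 slides of 2048 x 1536 px,
  difficulty 0.3, `roi_coverage = 0.2`, across three seeds, trained for 30
  epochs -- effectively to convergence, which the default backbone's convex
  objective permits. Convergence matters doubly here: the 0.90 confidence
  gate only passes a useful number of pseudo labels once the model is
  settled, and a converged convex model makes the step-1 vs step-2
  comparison reflect the data difference rather than initialization noise.

Other numerical conventions: probabilities are clipped to $[10^{-12}, 1]$
inside the loss; channel and feature standard deviations are floored at
$10^{-6}$; argmax ties (in predictions and heatmap summaries) are broken by
scheme label order, deterministically; `best_epoch` is 1-based, R's indexing
convention; ROI region plans that cannot be shelf-packed into the slide are
rejected with an error rather than silently truncated.

## Known limitations

* The default backbone's texture features are nearly D4-invariant, so for the
  synthetic textures the 8-fold augmentation mostly adds redundancy; it is
  kept because the contract (counts x 8, labels preserved, test tiles
  untouched) is part of the procedure under test, and real backbones are not
  orientation-invariant.
* Pseudo-label confidence is uncalibrated softmax confidence; temperature
  scaling and co-training are out of scope.
* Grid tiles straddling region boundaries have mixed texture; the confidence
  gate and the diagnosis filter remove most but not all resulting label
  noise. The audit manifest records every rejection reason so the residue is
  inspectable.
* Slide images are read whole into memory; the package targets desk-scale
  synthetic slides and exported ROI crops, not pyramidal gigapixel formats.
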