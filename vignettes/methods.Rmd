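---
title: "Patch-based mandibular fracture detection: models, phantoms and evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Patch-based mandibular fracture detection: models, phantoms and evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(mandfrac)
```

## The problem and the model

Mandibular fractures in cone-beam CT (CBCT) are hard to read: the dose is
low, tissue boundaries are noisy, and a nondisplaced fracture may be nothing
more than a thin band of slightly depressed density crossing the cortical
shell. `mandfrac` implements a three-stage, patch-based detection pipeline
for this problem, together with everything needed to exercise it end to end
at desk scale: a synthetic mandible-phantom generator with exact ground
truth, a training loop, scan-level inference, and a free-response ROC (FROC)
evaluation.

A scan is processed as overlapping cubic patches (64 voxels per edge at the
reference configuration; every patch edge must be divisible by
`2^(levels-1)`). The three stages are:

1. **Mandible segmentation.** A U-shaped encoder–decoder network predicts a
   per-voxel mandible probability for each patch. Three *adaptive grayscale
   window* channels are appended to the intensity channel first: per-patch
   percentile windows (0–40, 30–70, 60–100) that re-stretch soft tissue,
   cancellous bone and cortical bone respectively. A second head — global
   average pooling over the deepest encoder features followed by two fully
   connected layers — regresses the patch's relative position in the scan
   (each coordinate in [0, 1]), supervised with a smooth-L1 loss; the
   segmentation is supervised with voxel-wise binary cross-entropy (BCE).
   The two heads share one encoder, and the total stage-1 loss is the
   unweighted sum of the two terms (the relative weight is exposed nowhere
   because equal weighting trains stably on phantoms; both losses are on
   comparable scales).
2. **Fracture-line segmentation.** The scan is cropped to the bounding box
   of the predicted mandible (margin 10 voxels). For each patch, the raw
   intensity, the stage-1 decoder features and the stage-1 mandible logits
   are concatenated channel-wise and processed by a *cascade of two*
   U-shaped networks; the second network additionally receives the first
   network's logits and refines them. Both networks carry a BCE loss against
   a *softened* fracture target: the binary annotation is dilated with a
   1-voxel ball and Gaussian-filtered (sigma 0.5 voxel), then peak-rescaled
   to 1. Softening multiplies the number of positive voxels of a thin plane
   by roughly 3–7x, which stabilises training on extremely unbalanced
   targets; both parameters are exposed. Class balance is enforced by
   sampling patches containing nondisplaced-fracture voxels and patches
   without fractures at equal frequency.
3. **Patch classification.** A third network — the same encoder followed by
   GAP and two fully connected layers — classifies whether the patch
   contains *any* fracture (no distinction between nondisplaced and
   displaced), from the intensity, stage-1 features/logits and stage-2
   logits. This captures displaced fractures, whose wide dark gap is easier
   to recognise at patch level than to delineate voxel by voxel.

At inference, stage-2 probabilities are overlap-averaged over the sliding
window; stage-3 patch probabilities are placed at the patch centres and
interpolated trilinearly over that (rectilinear) lattice, clamped to the
lattice hull at the borders, and gated by the predicted mandible dilated by
3 voxels — patch-level fracture evidence away from bone is discarded.
Connected components (26-connectivity, minimum 10 voxels) of each binarized
map become *fracture proposals*; a proposal's confidence is the mean of its
source map over its voxels. Proposals from the two stages whose voxel sets
intersect are merged transitively (confidence = max of the parents), and a
final confidence threshold is applied. 26-connectivity is used because
fracture planes are thin and oblique; face-connectivity fragments them.

### Training recipe

Stages train successively with earlier stages frozen in evaluation mode (the
later stages consume "provided" features; joint fine-tuning is deliberately
not implemented). The optimizer is AdamW with decoupled weight decay 0.01
applied to convolution/linear weights only; mini-batches of 4 patches;
learning rates 0.005 (stage 1) and 0.002 (stages 2–3); a cosine-annealing
schedule with linear warm-up over the first 5 % of the epoch budget. An
*epoch* is a fixed number of randomly sampled patches (default 256), not an
exhaustive tiling — patch-based training has no natural epoch, and this
keeps the epoch a meaningful unit for the schedule. The returned model is
the one with the lowest validation loss; training always runs to the epoch
cap.

The networks themselves are a compact 3D CNN stack written for this package
(direct-loop 3x3x3 convolutions with hand-written backward passes, fused
batch-norm + leaky-ReLU kernels, 2x2x2 max pooling, transposed-conv
upsampling, skip connections by concatenation). The architecture descriptor
(encoder depth, base width doubling per level, head width) is part of every
stage object and is embedded in checkpoints; loading a checkpoint against a
mismatched descriptor is refused. Convolution arithmetic runs in single
precision; all gradients are verified against naive double-precision oracles
and finite differences in the test suite.

## The phantom generator

Clinical CBCT with annotated mandibular fractures is not distributable, so
the package generates phantoms that preserve the *detection geometry* of the
problem while remaining simple enough to have exact ground truth:

* the mandible surrogate is a half-torus ("horseshoe") — bright cortical
  shell (mean intensity 0.85 on the normalized scale), dimmer cancellous
  interior (0.45), dark background (0.15), additive Gaussian noise
  (sd 0.05);
* the default grid is 96 voxels per edge at 0.4 mm isotropic spacing —
  typical CBCT resolution, with the arch (radius 12 mm, bone radius 4 mm)
  scaled to fit;
* a **nondisplaced** fracture is a thin (0.8 mm) plane through the bone,
  oriented near the local arch tangent with up to 15 degrees of random
  tilt, whose voxels are depressed to near-background intensity;
* a **displaced** fracture rigidly translates all bone beyond its plane by
  2 mm along the plane normal; the ground truth marks the one-voxel
  interface band on both new surfaces. Geometry is evaluated by backward
  mapping, so multiple displaced fractures compose consistently;
* fracture sites keep a minimum angular separation (default 45 degrees)
  along the arch — distinct fractures are distinct locations;
* per-scan fracture counts for fractured phantoms are drawn as 1/2/3 with
  probabilities 0.63/0.29/0.08, and a fracture is displaced with
  probability 0.28, mirroring the published cohort composition; datasets
  default to about half fractured and half complete mandibles.

Every phantom is a pure function of its spec and seed; dataset scan seeds
are `master seed + scan index` so any scan regenerates in isolation.
Train/validation/test splits are 60/20/20 at scan level, stratified by the
set of fracture kinds present (the published stratification also uses
anatomical subregion, which has no phantom analogue).

What the phantoms deliberately do **not** model: teeth, condyles and
anatomical subregions; beam hardening, scatter and metal streaks; partial
fields of view. Tests passing on phantoms therefore demonstrate that the
*pipeline machinery and optimization work* — tiling, context plumbing,
fusion, scoring — not that the trained weights transfer to clinical CBCT.

## Evaluation protocol

Segmentation is scored with Dice `2TP/(2TP+FP+FN)` and IoU `TP/(TP+FP+FN)`
(two empty masks score 1; the identity `iou = dice/(2-dice)` is
property-tested). Detection is fracture-level: a proposal hits a fracture if
its voxels intersect the fracture's ground truth dilated by 2 voxels (thin
planes disagree at boundaries by a voxel or two); matching is greedy by
descending confidence with each proposal and each fracture matched at most
once; precision `TP/(TP+FP)` and sensitivity `TP/(TP+FN)` follow, with zero
denominators reported as 1 plus a degeneracy flag so batch evaluation never
aborts. The FROC curve re-runs matching at every distinct confidence and is
summarized by averaging the best sensitivity attainable at no more than
1/16, 1/8, 1/4, 1/2 and 1 false positive per scan (a step-function
convention; no interpolation between operating points). The FROC machinery
is verified against brute-force enumeration on randomized abstract
detection layouts.

## Numerical and design choices

* Working grid 0.4 mm isotropic; intensities percentile-normalized
  (0.5–99.5) to [0, 1] per volume — CBCT has no calibrated HU scale.
* Inference tiling uses stride = patch/2 (50 % overlap); training patches
  are randomly positioned. Stage-1 training draws half its patches centred
  on random mandible voxels (with jitter) so background does not dominate.
* Probability clamping in BCE: 1e-7. Batch-norm epsilon 1e-5, momentum 0.1;
  leaky-ReLU slope 0.01. He initialization throughout.
* Constant patches make the adaptive windows collapse; the window channels
  are then zero by contract. An empty mandible segmentation degrades to a
  full-volume crop with a warning. An empty fracture target yields an
  all-zero softened map.
* Stage-2 proposals are scored by the stage-2 map and stage-3 proposals by
  the stage-3 map; a merged proposal takes its best parent's confidence.
  Scoring stage-3-only proposals by the stage-2 map would silence exactly
  the detections stage 3 exists to contribute.
* Ties in greedy matching resolve toward the larger voxel overlap.

## Problem sizes used by the tests and the acceptance script

The scaled-down learning experiment trains width-4, 3-level networks on
32-cube patches from 20 phantoms (16 train / 4 validation) with 48 patches
per epoch and epoch budgets of 20/18/12 for stages 1/2/3, then evaluates on
5 held-out phantoms with stride-16 tiling. These sizes were chosen so the
whole experiment is a routine desk-scale run; under the test suite's fixed
seed it reaches mandible Dice above 0.9 and planted-fracture sensitivity of
at least 0.8 within one false positive per scan, with run-to-run spread
expected at this scale for other seeds. The oracle-substitution check replaces the three stages
with ground-truth oracles and verifies that the scan-level plumbing returns
exactly the planted fractures across kind mixes; it uses 16-cube patches so
the patch-centre lattice is fine enough that two well-separated fractures
never blur into one patch-level blob.

## Known limitations

* Two fractures closer together than roughly one patch width can merge into
  a single proposal through the patch-level (stage-3) evidence; the greedy
  matcher then counts one hit and one miss. This is intrinsic to patch-level
  classification, not a bug in the fusion.
* The compact CNN stack is CPU-only and single-threaded; it is sized for
  method verification, not clinical throughput.
* Phantom realism is deliberately limited (see above); no claim about
  clinical performance follows from phantom results.
* Displaced-vs-nondisplaced labeling of proposals and mandibular-canal
  awareness are out of scope.

## A minimal session

```{r example}
library(mandfrac)

scans <- phantom_dataset(10, phantom_spec(seed = 7), fractured_fraction = 0.5)
data <- list(train = scans[1:6], val = scans[7:8])

cfgs <- lapply(1:3, function(s) {
  train_config(s, max_epochs = 20, patch_size = 32, levels = 3, width = 4,
               patches_per_epoch = 48, val_patches = 16, seed = 7)
})
trained <- train_all_stages(data, cfgs)

pc <- pipeline_config(patch_size = 32, stride = 16)
res <- run_pipeline(scans[[9]]$volume, trained, pc)
proposals_table(res$proposals, scans[[9]]$volume$spacing)

ev <- evaluate_scans(list(list(proposals = res$all_proposals,
                               gt = scans[[9]]$fracture,
                               records = scans[[9]]$records)))
ev$froc
froc_auc(ev$froc)
```
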