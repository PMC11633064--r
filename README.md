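# mandfrac

Patch-based detection of mandibular fractures in cone-beam CT (CBCT)
volumes, in R.

Mandibular fractures are among the most common facial-skeleton injuries, and
CBCT — the modality increasingly used to assess them — trades dose for noise,
making thin fracture lines easy to miss. `mandfrac` implements a three-stage,
patch-based neural pipeline for this detection problem and everything needed
to exercise it end to end on synthetic data:

1. **Stage 1 — mandible segmentation.** 64³-voxel patches, expanded with
   three per-patch adaptive grayscale windows, are processed by a U-shaped
   network (BCE loss) whose shared encoder also feeds a GAP + 2-FC head
   regressing the patch's relative position (smooth-L1 loss).
2. **Stage 2 — fracture segmentation.** After cropping the scan to the
   predicted mandible, patch intensities ⊕ stage-1 decoder features ⊕
   stage-1 logits are processed by a cascade of two U-shaped networks (the
   second refines the first's logits; both BCE), trained with balanced
   sampling of fracture-positive and fracture-free patches against dilated,
   Gaussian-softened fracture targets.
3. **Stage 3 — fracture classification.** The same context plus stage-2
   logits feeds an encoder + GAP + 2-FC classifier deciding whether the
   patch contains any fracture.

Scan-level output: stage-2 probabilities are overlap-averaged, stage-3
patch probabilities are interpolated from the patch-centre lattice and
gated by the dilated predicted mandible; connected components of both maps
become fracture proposals (confidence = mean map probability over the
component); overlapping proposals from the two stages are united, and a
confidence filter is applied. Evaluation is fracture-level
precision/sensitivity, Dice/IoU for the mandible, and a FROC curve
summarized by the mean sensitivity at 1/16–1 false positives per scan.

Because clinical CBCT with fracture annotations is not distributable, the
package ships a synthetic phantom generator: a half-torus "mandible" with a
bright cortical shell, planted **nondisplaced** fractures (thin
low-intensity planes) and **displaced** fractures (rigid offset of the bone
beyond a plane), with exact ground-truth masks and a per-fracture manifest.
The neural network stack (3D convolutions with hand-written backward passes,
fused batch norm + leaky ReLU, AdamW, warm-up cosine schedule) is part of
the package and runs on a plain CPU.

## Worked example

Train the scaled-down configuration (width-4, 3-level networks, 32³
patches) on 20 phantoms and evaluate on 5 held-out phantoms:

```r
library(mandfrac)

set.seed(1)
scans <- phantom_dataset(25, phantom_spec(seed = 100), fractured_fraction = 0.5)
data  <- list(train = scans[1:16], val = scans[17:20])
test  <- scans[21:25]

mk <- function(sid, ep) train_config(sid, max_epochs = ep,
        patches_per_epoch = 48, patch_size = 32, levels = 3, width = 4,
        hidden = 32, val_patches = 16, seed = 1)
trained <- train_all_stages(data, list(mk(1, 20), mk(2, 18), mk(3, 12)))

pc <- pipeline_config(patch_size = 32L, stride = 16L, batch_size = 4L)
results <- lapply(test, function(sc) {
  r <- run_pipeline(sc$volume, trained, pc)
  cat(sprintf("scan: %d proposals (planted %d); mand dice %.3f\n",
              length(r$proposals), nrow(sc$records),
              dice(r$mandible_map$data >= 0.5, sc$mandible)))
  list(proposals = r$all_proposals, gt = sc$fracture, records = sc$records)
})
ev <- evaluate_scans(results)
print(ev$froc); cat("froc auc:", round(ev$auc, 3), "\n")
```

On this machine the run prints (about 10 minutes on one CPU):

```
scan: 1 proposals (planted 0); mand dice 0.984
scan: 1 proposals (planted 0); mand dice 0.984
scan: 1 proposals (planted 1); mand dice 0.981
scan: 1 proposals (planted 1); mand dice 0.980
scan: 1 proposals (planted 0); mand dice 0.984
        tau sensitivity fp_per_scan
1       Inf         0.0         0.0
2 0.8593448         0.5         0.0
3 0.8506083         1.0         0.0
4 0.8503926         1.0         0.2
5 0.8495087         1.0         0.4
6 0.8483967         1.0         0.6
froc auc: 1
```

Reading this: the learned mandible segmentation reaches Dice ≈ 0.98 on
held-out phantoms; sweeping the proposal-confidence threshold (`tau`), both
planted fractures are recovered before the first false positive appears, so
the averaged-sensitivity FROC AUC is 1.0 at this desk scale. (At the
default operating point `tau = 0.5` some low-confidence false positives
survive; the FROC sweep is the calibrated view.)

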