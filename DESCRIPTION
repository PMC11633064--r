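Package: mandfrac
Title: Patch-Based Detection of Mandibular Fractures in CBCT Volumes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A three-stage patch-based pipeline for detecting mandibular
    fractures in cone-beam computed tomography (CBCT) volumes. Stage 1
    segments the mandible in 3D patches and regresses each patch's relative
    position; stage 2 segments fracture lines with a cascade of two U-shaped
    networks conditioned on stage-1 features; stage 3 classifies whether a
    patch contains any fracture. Voxel-level and patch-level evidence are
    fused by connected-component proposal extraction, confidence filtering
    and stage union. Includes a compact 3D convolutional network stack with
    hand-written forward/backward kernels, a synthetic mandible-phantom
    generator with planted nondisplaced and displaced fractures and exact
    ground truth, successive stage training with AdamW and a warm-up cosine
    schedule, and free-response ROC (FROC) evaluation with averaged
    sensitivity AUC.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    oro.nifti,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
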