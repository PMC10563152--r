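---
title: "The apobdetect pipeline: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The apobdetect pipeline: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Nanowell cytotoxicity assays confine a few effector (immune) and target
(tumor) cells per well and image them every 5 minutes in phase contrast
plus fluorescence channels. Apoptosis is conventionally read out with
Annexin-V, but the signal is late and frequently absent even when the
phase images show unmistakable apoptotic-body (ApoBD) release. This
package detects apoptosis directly from the ApoBDs — small bright or
dark vesicles shed around the dying cell — and profiles each event:
when it started, which cell died, whether an effector contact preceded
it, and how the Annexin-V signal, when present, is distributed.

## Detection model

**Blob detection.** ApoBDs are compact, roughly circular, and appear in
either polarity against the background. We detect them as local maxima
of the scale-normalized Laplacian of Gaussian, `σ²∇²(G_σ * I)`, over a
log-spaced scale ladder, running both polarities and merging detections
closer than 2 px. The scale-normalization makes peak responses
comparable across σ, and the classical relation r = √2·σ converts the
detection scale into a circular area `π(√2σ)²` used downstream.

Tunable parameters (all on the 8-bit intensity scale after min–max
rescaling):

| parameter | default | meaning |
|---|---|---|
| `sigma_range` | 1.5–6 px | blob radii ≈ 2–8.5 px |
| `n_sigma` | 6 | scales on the log ladder |
| `threshold` | 30 | min scale-normalized response |
| `dedup_px` | 2 px | duplicate-merge distance |

The response threshold and ladder are free parameters of the classical
detector; the defaults were fixed against the bundled simulator, where
true bodies respond at ≳ 75 units and background texture mostly below
half of that. On other imagery they are the first knobs to revisit.

**Segmentation by adaptive flood fill.** From each blob centre we flood
4-connected pixels whose intensity differs from the *seed pixel* by at
most a tolerance, trying integer tolerances 1–50 and keeping the region
whose area is closest to the blob's circular area (ties toward the
smaller tolerance). Comparing to the seed pixel rather than a running
region mean keeps the operation monotone in the tolerance, which both
justifies the early-exit search and makes the "closest area" objective
unimodal.

**Shape filter.** Candidates are kept when the minor/major axis ratio of
the best-fit ellipse (eigenvalues of the pixel-coordinate covariance) is
at least 0.85 and the pixel area lies in [20, 200]. Both bounds are
inclusive — the borderline candidate is kept — and both are exposed in
the parameters. The aspect bound reads "low aspect ratio" as a
circularity-like quantity in (0, 1]; a single-pixel region has aspect 1
by convention, a collinear one aspect 0.

**Extracellular constraint.** Blobs whose centres fall inside the cell
mask, dilated by 3 px to absorb the bright halo fringe, are not ApoBD
candidates. Debris attached to the cell body is thereby rejected, which
matches how such detections are treated when curating segmentation
training data.

## Per-frame classification and onset calling

`baseline_classifier()` calls a frame ApoBD-positive when ≥ 1
extracellular candidate survives the filters; the score is the kept
count divided by a saturation constant (5). It is a training-free
stand-in for a deep per-frame classifier and deliberately modest — the
package's contract is any callable mapping a frame to (label, score),
and the cross-validation splitter (`grouped_kfold`) assigns folds at
nanowell level so frames from one well never straddle a train/test
boundary.

The onset detector requires `min_run = 3` consecutive positive frames;
the onset is the first frame of the first qualifying run. Three frames
(15 min) is the published operating point: shorter runs admit sporadic
false positives, and runs above four frames (> 20 min) start missing
real events. One wording of the protocol reads the onset as the first
positive frame anywhere in an event sequence; both behaviours are
available (`onset_rule = "run_start"` (default) or
`"first_positive"`). Note the deliberate asymmetry with contact
qualification: a killing contact requires *more than* three overlap
frames (≥ 4), while onset requires ≥ 3 — the two rules genuinely
differ and are configured separately.

The evaluation metric (`frame_error`) charges the absolute onset
difference in frames, and the full sequence length (10 for the standard
protocol) for a missed or false event.

## Association and interaction analyses

ApoBDs are mapped to cells by least average centroid-to-centroid
distance; exact ties go to the smaller cell id. Distance to the cell
*boundary* is arguably more physical for large cells, and a variant
could be added behind the same interface, but centroid distance is the
documented default. The per-frame winners over a 3-frame window starting
at onset are resolved by strict-majority vote; without a strict majority
the cell with the smallest mean of its per-frame mean distances wins.
Frames without ApoBD detections abstain.

Annexin-V validity is `IoU(otsu(annexin), cell mask) > 0.1` (strict; a
channel with no signal at all is scored IoU 0 and invalid). Distribution
is *even* when the IoU exceeds 0.5 and *localized* otherwise, again
strict at the boundary. The immune-synapse region is delineated as the
intersection of the two contact cells' masks each dilated by 3 px — a
documented stand-in, since the upstream assay does not publish a
formula. Localization PCC is computed over the whole nanowell (not a
crop) against the cell and synapse masks rendered as 0/1 images; the
whole-well choice keeps the statistic independent of an arbitrary crop
box at the cost of diluting both correlations equally.

## Numerical conventions

* Otsu thresholding maximizes the between-class variance over the
  *distinct observed values* (no 256-bin quantization), and binarization
  is strictly `pixel > threshold`, so ties fall to background. Ties in
  the variance objective resolve to the smallest threshold.
* Pixel coordinates are 1-based (row, col) matrices as native in R;
  frame indices and onset/contact frames are 0-based, matching the
  on-disk layout `frame_<t>_<channel>.tif`.
* Connectivity is 4-connected everywhere (flood fill, component
  labelling).
* All randomness flows through explicit integer seeds; the simulator
  restores the caller's RNG state.

## Weak-label generation and erasure

`generate_weak_labels()` turns a frame into a segmentation-training
entry: kept candidates become instance annotations; rejected candidates
and blob detections without a kept mask are erased from the 8-bit image
so the training image contains only annotated objects. Erasure replaces
each pixel of the erase region with the disk-kernel median of the
*surrounding background* (pixels outside the region, kernel radius 3
growing until support), followed by one plain disk-median pass. A plain
median blur is edge-preserving and only removes objects smaller than its
kernel, so the masked variant is required to level oversized rejects;
the specified single-pass operator is available unchanged as
`median_remove_in_roi()`. Erasure acts only inside an attention mask —
by default the blob footprints plus dilated rejected masks, standing in
for a classifier-saliency (Grad-CAM-style) region — and never touches
kept-instance pixels. Two corollaries: objects the detector never sees
cannot be erased, and the levelled region matches the local background
in *level* (residual contrast well under one gray level) while
individual pixels keep fluctuating with the sensor noise.

## The simulator

`simulate_video()` renders stylized nanowells: cells as dark textured
disks (radius 8–14 px) with a 2 px bright halo on a flat background with
Gaussian sensor noise (σ = 30 on the 16-bit scale); ApoBDs as uniform
disks of random polarity with pixel areas drawn from the configured band
(default 20–200 px, the detection band), released in a ring around the
apoptotic cell from the onset frame onward and jittered between frames;
fluorescence channels as bright disks over the cell masks; and an
Annexin-V channel that is nonzero only for Annexin-positive events
(probability 0.3, the fraction observed in killing assays), drawn either
evenly over the dying cell or as an off-centre blob toward the contact
direction. A killing event forces the first effector to overlap the
target for 5 frames ending just before onset. Everything about the truth
— tracks, masks, instances, contacts, flags — is returned alongside the
video.

What the simulator does *not* emulate: realistic phase-contrast optics
(PSF, shade-off, out-of-focus ApoBDs), cell morphology change during
apoptosis, ApoBDs overlapping cells or each other, debris, nanowell
walls, photobleaching. Passing tests on simulated data therefore
demonstrates the correctness and internal consistency of the pipeline's
rules and geometry, not classifier-grade performance on real imagery —
which is exactly why the deep models the pipeline was designed around
remain pluggable.

`simulate_label_sequences()` implements the synthetic evaluation
protocol at its published scale: 300 event and 300 non-event sequences
of 10 frames with at most half the frames positive. The positive count
is drawn uniformly over its feasible range (the protocol does not state
a distribution), and arrangements are rejection-sampled until the class
constraint holds; event onsets are the first frame of the first
qualifying run.

## Problem sizes in the test suite

The suite checks the metric operators against independent brute-force
oracles on 10⁴ randomized small instances each; the sequence protocol at
its full 300 + 300 scale; parameter recovery end-to-end on 50 simulated
videos at the default 256 × 256, 10-frame configuration (onset within
±1 frame and apoptotic-cell identity, both ≥ 90%); and Annexin-rate
recovery on 200 small simulated events against a 3-standard-error
binomial band around 0.3.

## Known limitations

* The baseline classifier's thresholds are calibrated on the simulator's
  contrast statistics; real phase-contrast data will need either
  re-tuning or a trained classifier plugged into the same contract.
* Association can mis-assign when the dying cell sits against the well
  edge: its ApoBD cloud is then biased toward the well interior, and a
  contacting effector on that side can win the least-average-distance
  vote.
* The overlap tracker is greedy and single-hypothesis; it is a stand-in
  for a dedicated cell detection/tracking module, not a contribution.
* Cells are segmented from fluorescence only; a phase-only well has no
  cell masks, and every blob is then treated as extracellular.
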