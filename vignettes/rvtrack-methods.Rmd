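---
title: "Automated tricuspid annular displacement: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated tricuspid annular displacement: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Right-ventricular (RV) systolic function is most often screened on 2D
echocardiography through the longitudinal descent of the tricuspid annulus
(TAPSE, tissue-Doppler S′). Those conventional measures need extra
acquisitions and careful cursor placement. `rvtrack` implements a fully
automated alternative: a convolutional network segments the lateral and
septal tricuspid annulus on every frame of an apical four-chamber cine loop,
the annulus is tracked as a point through time, and two displacement indices
summarise RV longitudinal function per case.

## The pipeline

### Segmentation model

The segmenter is a U-net in which every convolutional block is a residual
module: two 3×3 convolutions with batch normalisation and ReLU, plus an
identity shortcut (a 1×1 projection where the channel count changes). The
contracting path halves resolution with 2×2 max-pooling and doubles channels;
the expanding path upsamples with learned 2×2 transposed convolutions and
concatenates the same-resolution encoder features; a final 1×1 convolution
produces `C` per-pixel class logits. Defaults: `C = 3` (background, lateral
annulus, septal annulus), depth 5, 32 base channels, 224 px input.

`C = 3` is a deliberate choice: the two annular landmarks are tracked
separately downstream, so one network predicts both classes rather than
training two binary networks. The class-weight vector generalises the binary
annular/non-annular weighting: `W = (0.2, 0.8, 0.8)`, down-weighting the
overwhelmingly prevalent background class. Setting `loss_config(c(0.2, 0.8))`
with `n_classes = 2` reproduces a binary variant.

Training minimises the class-weighted softmax cross-entropy

$$\mathrm{Loss}(x, i) = -W[i] \, \ln \frac{e^{x[i]}}{\sum_j^{C} e^{x[j]}},$$

where `x` is the logit vector at a pixel and `i` its true class. The
reported loss is the plain mean of the per-pixel terms over all pixels in
the batch (not normalised by the weight mass); this choice changes the
numeric scale of the loss but not its gradients' direction, and it is stated
here because loss values are only comparable under the same reduction.
Optimisation is RMSProp (`lr = 1e-3`, `alpha = 0.99` by default — the
conventional settings, since no specific values are canonical for this
task). The forward/backward passes and RMSProp are implemented in the
package itself (R orchestration over Armadillo/BLAS convolution kernels), so
training is fully deterministic under a seed on a single thread.

### Preprocessing and augmentation

Frames are resampled so the longer side matches the network input, zero-
padded to square, and min–max rescaled to [0, 1] per frame (a constant frame
maps to zeros rather than erroring). Training-time augmentation applies one
geometric transform to image and mask together — random zoom (0.9–1.1),
rotation (±15°), crop, horizontal/vertical flip (p = 0.5 each) — with
nearest-neighbour interpolation for the mask so labels stay integer, and
adds Gaussian noise (σ = 0.01) to the image only. The ranges are
conventional "aggressive but in-frame" values; none are canonical. A draw
that pushes every annular pixel out of the crop is re-drawn (up to 5
attempts) rather than trained on.

One caveat discovered during development: when the class coding is
side-specific (lateral vs septal), horizontal flips move the lateral
landmark to the septal side of the image while keeping its lateral label,
which destroys the positional cue the network needs to tell the two
otherwise identical-looking landmarks apart. The phantom training helper
(`train_segmenter()`) therefore defaults to no augmentation; when
augmentation is enabled for side-specific training, flips should be
disabled.

### Tracking and indices

The annulus position on each frame is the center of mass of **all** pixels
carrying the class label — no connected-component filtering, by definition;
filtering to the largest component is available as an explicit option but is
not the default. An empty frame yields a missing position (a value, not an
error). Per-coordinate median smoothing (default window 3 frames,
configurable) removes single-frame segmentation dropouts without flattening
the systolic excursion at typical frame counts; at the sequence edges the
window shrinks, and missing frames are excluded from each window rather than
interpolated — interpolation would invent motion.

Two indices are computed per annulus, in cm via the pixel spacing:

- **LTAD** (linear tricuspid annular displacement): the maximum over *all*
  frame pairs of the Euclidean distance between tracked positions. The
  all-pairs reading is used (rather than anchoring one end at end-diastole)
  because it is the only reading independent of cycle-phase labelling.
- **CTAD** (circumferential tricuspid annular displacement): the total
  bidirectional path length, i.e. the sum of Euclidean steps between
  consecutive tracked frames. Missing frames are skipped without bridging
  inflation control; if the longest missing run exceeds the median window,
  the case is flagged invalid rather than silently reported.

Pixel spacing must come from input metadata. Without calibration the indices
are reported in px with an explicit `unit = "px"` tag — never silently as cm.

### Cross-validation

`make_folds()` partitions *cases* (never frames) into k near-equal folds;
`run_cv()` trains a fresh model per fold on the other folds and predicts only
held-out cases. A leakage guard asserts — as a hard failure — that no case is
ever predicted by a model that saw it in training.

### Evaluation statistics

- Bland–Altman: mean paired difference and limits of agreement at
  mean ± 1.96 SD (sample SD, n − 1).
- ICC: ICC(2,1), two-way random effects, absolute agreement, single
  measurement — the standard inter-observer model; the F-based 95% interval.
  The form matters: consistency ICC would hide a constant bias between
  methods. Zero between-case variance makes the coefficient undefined and is
  reported as `NA`.
- ROC/AUC: Mann–Whitney rank formulation with midrank ties; oriented so that
  *lower* displacement indicates dysfunction. CI by DeLong (default) or a
  seeded stratified bootstrap (2000 resamples).
- Operating point: among candidate cutoffs (interior midpoints of sorted
  unique scores plus the two all-or-none boundaries), keep those with
  sensitivity strictly above the floor (default 0.80), then maximise
  specificity; ties break toward higher sensitivity, then the lower cutoff.
  "Maximise sensitivity (>80%)" is ambiguous between this reading and
  "pick the max-sensitivity point"; the constrain-then-maximise-specificity
  reading is used because it reproduces operating points whose sensitivities
  cluster just above the floor. If no cutoff attains the floor, the
  max-sensitivity point is reported with `floor_attained = FALSE`.
- Group comparison: two-sided unpaired Student t test, pooled variance by
  default (Welch available); tertile stratification at the empirical
  33.3/66.7 percentiles with a one-way ANOVA trend test.
- No multiple-testing adjustment is applied; p values are reported raw with
  two-sided α = 0.05.

## The synthetic phantom

Clinical cine loops with annotations are not distributable, so the package
ships a generator whose ground truth is known by construction. Each case is
a sector-shaped (90°, typical for phased-array imaging) image with a
radially decaying background under multiplicative unit-mean Rayleigh-like
speckle, containing two small bright Gaussian landmarks. Each landmark moves
sinusoidally along a fixed direction with configurable peak excursion, so
the configured amplitude *is* the ground-truth LTAD (the analogue of
systolic annular descent); truth masks are disks of uniform radius centred
on the (sub-pixel) truth positions, rasterised by rounding, which bounds the
mask-centroid quantisation error at 0.5 px. Identical configuration and seed
give bit-identical output. Defaults: 256 px frames at 0.05 cm/px, 30 frames
per cycle (frame-rate and cycle coverage are conventions, not canonical
values), lateral amplitude 1.8 cm and septal 1.0 cm — near the means of
normal clinical cohorts; `generate_cohort()` draws dysfunctional cases
(assigned deterministically to the lowest indices, `floor(n · fraction)` of
them) from a low lateral-amplitude range (0.8–1.4 cm) and normals from a
high range (1.6–2.4 cm), with septal amplitude fixed at 0.55 of lateral,
mirroring the roughly halved septal excursion seen clinically.

What the phantom does *not* emulate: anatomy (chamber walls, valve
leaflets), through-plane motion, probe motion, shadowing and dropout,
inter-vendor intensity characteristics, or physiologic beat-to-beat
variability. During development a variant with static echogenic wall bands
was tried and rejected: the network anchored on the static texture and
tracked worse. Passing phantom tests therefore demonstrates that the
*pipeline machinery* (training, segmentation, tracking, indices, statistics)
is correct and self-consistent, not that the trained weights transfer to
clinical images — clinical accuracy claims require clinical data.

A deliberate simplification with a real consequence: the two landmarks look
identical, so the network must learn their identity from absolute position
(feasible thanks to zero-padding cues and the sector geometry, given
sufficient receptive field — hence depth 5 in the scaled-down protocol
below). In clinical images the two annular regions have distinct local
anatomy, making the class assignment easier than in the phantom.

## Problem sizes used by the test-suite protocols

Two scaled-down protocols are exercised by the tests, chosen as the smallest
sizes at which each property is meaningfully demonstrated:

- *Reproducibility*: 20 cases, 64 px at 0.2 cm/px, 12 frames; a depth-4,
  6-channel network trained 6 epochs. Repeated runs of `quantify` must agree
  exactly (ICC 1, zero-width limits of agreement) — inference is a single
  deterministic pass with no test-time augmentation, so the agreement is
  bitwise regardless of segmentation quality.
- *Parameter recovery*: 24 cases (8 dysfunctional), 128 px at 0.1 cm/px, 30
  frames, label radius 4 px; a depth-5, 8-channel network trained 15 epochs
  per fold (6 frames per case per epoch, batches of 8, RMSProp lr 1e-3)
  under k = 3 case-level cross-validation. Tracked lateral LTAD is required
  to fall within 15% of the configured amplitude for at least 80% of cases,
  and with disjoint amplitude ranges the cohort must separate perfectly
  (AUC 1, sensitivity = specificity = 1 at the constrained operating point).
  The label radius matters at this scale: 3 px disks leave too few predicted
  pixels for a stable centroid, 4 px disks recover amplitudes to within a
  few percent.

## Numerical choices and degenerate inputs

- Batch normalisation uses batch statistics during training (momentum 0.1
  running averages, ε = 1e−5) and stored running statistics at inference,
  preserving single-pass determinism.
- He initialisation for convolutions; unit gamma / zero beta for batch norm.
- Softmax is computed with max-subtraction; log-probabilities are floored at
  1e−300 so a zero-probability true class yields a large finite loss, while
  a non-finite training loss aborts with learning-rate guidance.
- Median windows must be odd; window 1 is the identity. A case whose frames
  are all missing raises a tracking-failure error.
- Candidate ROC cutoffs at interior midpoints are invariant to monotone
  score perturbations within gaps.
- ICC with identical columns short-circuits to exactly 1 (the residual and
  column mean squares vanish identically in floating point), which makes the
  reproducibility property assertable as an exact identity.

## Known limitations

- The phantom's speckle is a convenience model (multiplicative Rayleigh-like
  noise), not a physical ultrasound simulation; robustness, not realism, is
  what it tests.
- Training the segmenter on CPU in R is practical only at reduced sizes; the
  default 224 px / depth-5 / 32-channel configuration is provided for
  completeness but expects patience or smaller images.
- DICOM and NRRD containers are not read; supported inputs are NIfTI and
  PNG stacks with a JSON sidecar.
- The indices quantify longitudinal annular motion only; they are surrogates
  for, not measurements of, RV ejection fraction.
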