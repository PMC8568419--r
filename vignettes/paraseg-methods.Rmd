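---
title: "Segmenting paravertebral muscle on abdominal CT: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Segmenting paravertebral muscle on abdominal CT: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paraseg)
```

## The problem

Cross-sectional area of the paravertebral muscles — psoas, quadratus
lumborum, and the paraspinal group — measured on axial CT at the L3/L4 level
indexes whole-body skeletal muscle mass and is a practical imaging biomarker
for sarcopenia in oncology. Manual delineation is slow and has poor
inter-rater consistency, which motivates automatic semantic segmentation.
`paraseg` implements a complete pipeline for this task: ground-truth
construction from manual regions of interest (ROIs), CT-aware data
augmentation, a configurable U-Net, a seeded training loop, and a repeated
holdout cross-validation harness — plus a synthetic phantom generator so that
every stage can be exercised and tested without clinical data.

## Ground truth: ROI restricted to the muscle HU window

CT attenuation is expressed in Hounsfield units (HU), with water at 0 and air
near −1000. Skeletal muscle conventionally occupies the window
**[−29, +150] HU**. The training target is not the raw manual ROI but the ROI
intersected with this window:

$$\mathrm{GT}(p) = \mathrm{ROI}(p) \cdot \mathbf{1}\{-29 \le \mathrm{HU}(p) \le 150\},$$

with both bounds inclusive (the standard body-composition convention; the
window is configurable via `apply_hu_filter(hu_lo, hu_hi)`). This removes
intramuscular fat and any bone or vessel accidentally enclosed by the ROI
contour. Filtering is idempotent and the result is always a pixel-wise subset
of the ROI — both properties are enforced by tests.

Network inputs are mapped from HU to $[0,1]$ by the fixed linear map
$(\mathrm{HU} + 1024)/2048$, clipped outside. A fixed map (rather than
per-image min–max) is dataset-independent, deterministic, and preserves the
contrast of the muscle window across slices. `unet_predict()` refuses raw-HU
input so the two scales cannot be mixed silently.

## Patient-level 6:2:2 splitting

Patients — not slices — are the sampling unit: all four slices of a subject
go to the same partition, eliminating leakage of patient-specific anatomy
between training and evaluation. Counts use round-half-up for the training
and validation fractions with the remainder as test, so 256 patients split
6:2:2 into 154/51/51 patients, i.e. 616/204/204 slices at 4 slices each.

## CT-aware augmentation

Generic photometric augmentation is inappropriate for CT, where intensity
carries calibrated physical meaning. The augmentation here is purely
geometric, emulating patient positioning variation: a translation of at most
5% of the image side per axis, an optional horizontal flip, and a rotation of
at most ±20° about the image centre, with all parameters drawn uniformly at
random. The same transform is applied jointly to slice and mask; composition
order is fixed (flip, then rotation, then shift). The image is resampled
bilinearly with out-of-frame regions set to air (−1000 HU); the mask uses
nearest-neighbour so it stays strictly binary. Identity parameters reproduce
the input bit-for-bit, and a double horizontal flip is an exact involution —
both are tested, as is the consistency between transforming the mask directly
and re-deriving it by HU-filtering the transformed image (Jaccard ≥ 0.98 over
100 random draws on a noiseless phantom).

Augmentation is materialised offline with `augment_dataset(factor = 5)`: each
original is retained once and given `factor − 1` independently transformed
copies (616 → 3080 at the default factor), with full provenance (source index
and parameters) recorded so any copy can be replayed exactly. The ×5 set is
fixed, not resampled per epoch, mirroring a fixed augmented training corpus.
The ground truth is HU-filtered *before* augmentation; the filtered mask is
transformed as-is rather than re-filtered against the warped image (the two
agree to Jaccard ≥ 0.98, which is what the consistency property checks).

## The network

The U-Net encoder has $L$ levels of two same-padded 3×3 convolutions with
leaky-ReLU activations (negative slope 0.01), separated by 2×2 max pooling
with stride 2. The number of filters at level $i$ follows the geometric rule

$$n_i = n_\mathrm{base} \cdot 2^{\,i-1}, \qquad i = 1, \dots, L,$$

with $n_\mathrm{base} \in \{16, 32\}$ the grid of interest and 32 the
default. The decoder mirrors the encoder with 2×2 stride-2 transposed
convolutions and skip concatenation from the matching encoder level; the head
is a 1×1 convolution to two channels followed by a per-pixel softmax, and the
predicted mask is the channel-wise argmax with exact ties going to background
(deterministic and conservative). Default depth is $L = 5$; the input side
must be divisible by $2^{L-1}$ so pooling is exact, which is validated at
build and at every forward pass.

Design points worth making explicit:

* **No batch normalisation.** Gradients are accumulated one slice at a time
  within each batch of 4, which makes cross-batch statistics ill-defined.
  Instead, an optional *instance normalisation* (per-sample, per-channel
  standardisation with learned gain and offset after each 3×3 convolution) is
  available via `unet_config(norm = "instance")`. It is off by default — the
  plain architecture is the reference and trains well on this task — but
  instance normalisation markedly accelerates optimisation when the step
  budget is very small, and is the batch-size-independent normalisation
  medical segmentation pipelines typically reach for.
* **Initialisation** is seeded He-uniform ($\pm\sqrt{6/\mathrm{fan_in}}$),
  the standard choice for ReLU-family activations; biases start at zero.
* All layer arithmetic (convolution via im2col + GEMM, pooling, transposed
  convolution) is implemented in compiled code with analytic gradients; the
  backward pass is verified against central finite differences in the test
  suite.

## Training

Adam (learning rate $10^{-4}$ by default, batch size 4) minimises per-pixel
categorical cross-entropy — the natural companion of a softmax head, and
deliberately a *different* quantity from the monitored metric. After every
epoch the foreground mean intersection-over-union (mIOU) is computed on the
un-augmented validation set; the checkpoint with the best validation mIOU is
returned. Training stops at 1000 epochs or after 100 epochs without strict
improvement; after 100 non-improving epochs the learning rate is multiplied
by 0.1 (configurable). Any strictly greater validation mIOU resets both
patience counters (min-delta 0). The loop is fully deterministic given its
seed: weight draw, data order, and augmentation are all seeded.

## Evaluation and model selection

The headline metric is the foreground Jaccard index $|A \cap B| / |A \cup
B|$, averaged per image (each slice weighted equally, not pooled over
pixels). When prediction and reference are both empty the score is defined as
1 — perfect agreement on an empty slice is not penalised; this convention
affects per-image averages and is stated wherever scores are reported.
`confusion_map()` renders the conventional overlay: true positives white,
false negatives green, false positives red, true negatives black, with counts
attached that exactly satisfy $J = TP/(TP+FP+FN)$.

`run_cv()` performs repeated holdout cross-validation: each of 3 rounds draws
a fresh seeded patient-level 60/20/20 split, trains every model in the
$n_\mathrm{base} \in \{16,32\} \times \{\mathrm{DA}, \mathrm{no\ DA}\}$ grid
from a fresh initialisation, and scores the round's held-out test slices. The
final per-model score is the unweighted arithmetic mean of its round scores;
the selected model maximises that mean, with the lower across-round standard
deviation breaking ties (stability preferred). The per-model uncertainty
reported within a round is the standard deviation across test images, and is
labelled as such.

## The synthetic phantom

No public cohort exists for this task, so the package ships a parametric
phantom (`phantom_spec()`, `generate_cohort()`) that emulates the features
the pipeline actually depends on: an elliptical body cross-section on an air
background (−1000 HU), fat-equivalent soft tissue (−100 ± 20 HU), a vertebral
body of bone (700 ± 150 HU), and six muscle compartments — bilateral psoas
(ellipses), quadratus lumborum (small ellipses), and paraspinal crescents
(ellipse differences) — with muscle at 60 ± 20 HU, inside the muscle window
and with realistic contrast to fat. Additive Gaussian acquisition noise
(sd 10 HU) is applied before integer quantisation, matching the integer
storage convention of CT. Muscles are kept inside a subcutaneous fat rim and
separated from the vertebra by a fascial margin, so tissue classes never
touch in a way real anatomy would not.

Each patient draws one uniform ±10% jitter on compartment centres and axes,
shared by its 4 slices (so patient-level splitting is meaningful); noise is
redrawn per slice. Tissue HU means/sds were chosen once from standard CT
tissue ranges. The phantom deliberately does **not** model vertebral
morphology, contrast kinetics, beam hardening, rings, or inter-organ
variability: passing tests on phantoms demonstrates that the pipeline's
mechanics (ground-truth construction, augmentation, optimisation, scoring)
are correct, not that the trained weights transfer to clinical CT.

## Scaled-down training runs

The full protocol — 512×512 slices, 3080 augmented images, up to 1000 epochs
— is far beyond what a test suite should run. The package's acceptance
exercises use a scaled-down surrogate chosen once: 40 phantom patients (160
slices) at 128×128, $n_\mathrm{base} = 8$, $L = 4$, batch 4, at most 30
epochs, all seeded. One hyper-parameter must scale with the budget: the
learning rate. The full protocol takes roughly $2 \times 10^5$ Adam steps;
the surrogate takes about 720. Since Adam's per-parameter step magnitude is
bounded by the learning rate, total parameter travel scales like
$\mathrm{lr} \times \mathrm{steps}$, so the surrogate uses $10^{-3}$: at the
protocol default $10^{-4}$ the optimiser is still deep in the
all-background regime after 30 epochs on this class-imbalanced target
(roughly 7% of pixels are muscle), whereas the larger rate reaches
convergence within the budget. The acceptance criterion is a held-out
foreground mIOU of at least 0.85 on unseen phantom patients, with a
direction check that augmentation does not hurt when the training set is
thinned to 10 patients.

A tiny-scale version of the cross-validation harness (8 patients at 32×32,
3 rounds, a reduced model grid) checks the bookkeeping that does not depend
on scale: the final score is the exact unweighted mean of round scores, and
identical seeds reproduce the report bit-for-bit.

## Numerical choices and degenerate inputs

* Softmax is computed with the max-subtraction trick; per-pixel channel sums
  are within $10^{-5}$ of 1 by test.
* Max-pooling resolves ties by a fixed scan order; argmax prediction ties go
  to background; both make inference deterministic.
* `jaccard()` validates binarity and shape and defines the both-empty case
  as 1.
* Empty training or validation sets, validation sets sharing a patient with
  training, non-square or indivisible inputs, uncalibrated image files,
  inverted HU windows, and ratio vectors not summing to 1 are all rejected
  with errors naming the violated constraint.
* HU images are stored on disk as 16-bit grayscale TIFF holding
  $\mathrm{HU} + 1024$ with the rescale slope/intercept recorded in a TSV
  manifest (the same linear calibration contract DICOM uses); masks are 8-bit
  PNG. Reading an image without calibration is an error, never a silent
  identity assumption.

## Known limitations

* The phantom is geometrically simple; results on it bound only the
  pipeline's correctness, not clinical performance.
* Training is CPU-bound and single-threaded apart from BLAS; the full
  512×512 protocol is supported but slow — the package's value at full scale
  is the protocol's exactness and reproducibility, not speed.
* Only binary (background/muscle) segmentation is implemented; multi-class
  body composition and 3-D volumes are out of scope.
* Slice selection at L3/L4 is taken as given in the input manifest, as is
  any exclusion of poor-quality slices.
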