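---
title: "Segmenting with missing MRI sequences: the input-level dropout model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Segmenting with missing MRI sequences: the input-level dropout model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`ildseg` trains a single voxel-wise lesion segmentation model for
multisequence brain MRI that remains usable when one or more of its input
pulse sequences is absent at the site where it is deployed.

The input is a 2.5D slab stack: for each of the `S` co-registered sequences,
`k = 2·half + 1` contiguous axial slices centred on the slice being
predicted, concatenated along the channel axis (`S·k` channels; 20 for the
default four sequences × five slices). The network predicts the probability
map of the centre slice only; through-plane context comes from the slab, not
from 3D convolutions.

The central mechanism is *sequence-level input dropout*. At every training
step, each slab independently draws the number of sequences to drop, `d`,
from a configurable distribution over `{0, …, S−1}` (default uniform), then a
uniformly random subset of that size. All `k` channels of a dropped sequence
are zeroed — a sequence is dropped atomically, never slice-by-slice, because
a partially-zeroed slab corresponds to no physical acquisition — and every
surviving channel is multiplied by `1/(1−p)` with `p = d/S`, so the expected
total input activation matches the complete input. The all-dropped pattern
(`p = 1`) is inadmissible: it would hand the network an all-zero tensor.
Exactly the same zero-fill and reweighting is applied at inference, driven by
a declared availability pattern (a bit string such as `0111`), so a missing
sequence never requires retraining.

Two properties pin the algebra down and are asserted by the test suite: for a
channel-balanced slab the post-dropout total intensity is conserved exactly
for every admissible pattern, and for any fixed slab the expectation of the
post-dropout stack over uniformly random dropped subsets equals the input
stack.

## The network

The backbone is a compact fully-convolutional 2D network: a stem of 3×3
convolutions, a pyramid of parallel 3×3 atrous (dilated) convolutions at
rates `{1, 2, 4}` whose outputs are concatenated and fused by a 1×1
convolution, and a 1×1 sigmoid head. Dilated convolutions enlarge the
receptive field without downsampling, so the output keeps the input's
spatial shape and no decoder is needed. The design choice here was
deliberate: the scientific claim under test concerns the *input layer*, not
the backbone, so we favour a network small enough to train on a CPU in
minutes while keeping the architectural ingredient that matters (the dilated
pyramid); width (`base_width`), depth (`n_stages`) and rates are
configuration, so the same code scales up.

The forward/backward passes are implemented as shifted matrix
multiplications over precomputed index maps (zero padding; one matrix per
kernel tap), optimised with Adam. Backpropagation is verified against
numerical gradients in the test suite. Initialisation is He-normal and fully
seeded; the output head's bias starts at −2 so the initial foreground prior
is low, which stabilises the first epochs under heavy class imbalance.

Training hyperparameters that matter, with defaults and rationale:

* `loss_name = "bce_dice"` — weighted cross-entropy plus soft Dice. Lesions
  occupy a tiny voxel fraction; pure cross-entropy tends to the empty
  segmentation, and the soft-Dice term supplies a scale-free overlap
  gradient. `foreground_weight = 8` balances the cross-entropy term.
* `learning_rate = 0.01`, `batch_size = 8` — stable for the default width on
  z-scored inputs.
* `epochs = 12` by default; the packaged experiments use 6–8, which is where
  the phantom task saturates.

Intensities are z-scored per sequence within the brain mask before training
and inference, and dropout is applied after normalisation, so imputed zeros
coincide with the masked background mean. Missing (all-zero) sequences are
excluded from normalisation. The operation is idempotent and refuses
zero-variance inputs.

## The phantom generator

No clinical volumes ship with the package; the generator produces the study
conditions instead. Each subject is an ellipsoidal "brain" containing a
smooth two-tissue background (low-pass-filtered noise thresholded into two
intensity levels — an atlas-free stand-in for grey/white matter), one to
three enhancing metastases (axis-aligned ellipsoids with semi-axes drawn
from 2–5 mm; their union is the ground truth), curvilinear vessel-like tubes
(radius 0.8 mm), and additive Gaussian noise (sd 0.3 against tissue levels
1.0/1.5 and lesion contrast 3 — roughly SNR 10, i.e. clearly visible but not
noise-free lesions). Everything is a deterministic function of the
configuration seed.

The four default sequences mimic a metastasis protocol in one crucial
respect: *which* structures are bright *where*. Lesions enhance on the
post-contrast T1 gradient-echo (`t1_bravo`, contrast +3) and post-contrast
T1 fast spin echo (`t1_cube_post`, +3), weakly on FLAIR (+1) and not on the
pre-contrast T1 (`t1_cube_pre`, 0). Vessels are bright on the gradient-echo
(+3) and FLAIR (+2) but suppressed on both fast-spin-echo sequences — the
flow-suppression asymmetry that makes vessels the classic false-positive
source. Consequently no single sequence separates lesion from vessel: the
model must combine sequences, and a model deprived of the clean
`t1_cube_post` channel must fall back on the cross-sequence rule "bright on
`t1_bravo` but not vessel-bright elsewhere". This is exactly the ambiguity
the input-dropout training is meant to survive.

What the phantoms do *not* emulate: anatomy (no atlas, no cortex/ventricles),
MR physics (no TR/TE modelling, no bias fields, no motion), irregular lesion
shapes, and the site-to-site intensity shifts of real multicenter data. A
passing experiment therefore shows that the dropout mechanism, training loop
and evaluation protocol work and interact correctly — it does not certify
clinical performance.

## The evaluation protocol

Per case: voxel-wise ROC and AUC (trapezoidal rule) over brain-mask voxels;
the operating threshold selected by maximising the Youden index
(sensitivity + specificity − 1) on the *pooled* voxels of a validation
cohort; Dice, IoU, precision, recall and FPR at that threshold; and
lesion-wise false-positive counts on the 26-connected components of the
thresholded map (face/edge/corner adjacency), without a size limit and
excluding components below 10 mm³. Cohorts are summarised as mean ± sd per
metric plus a vertically averaged ROC: per-case sensitivity interpolated on
a fixed FPR grid, mean ± 1.96·sd/√n at each grid point. Two models are
compared by the two-sided Wilcoxon rank-sum test on per-case values at
α = 0.05.

Numerical and convention choices, each deliberate and tested:

* Thresholding is a closed lower bound (voxel included iff probability ≥
  threshold); Youden candidate thresholds are the observed probability
  values plus {0, 1}, with ties in J broken toward the larger threshold.
* A predicted component is a false positive iff its voxel-wise product with
  the ground truth is identically zero. The size filter is applied before
  counting; it is a detection convention (a sub-10 mm³ blob is "not a
  reported lesion"), not a morphological cleanup of the mask.
* Degenerate voxel counts follow fixed conventions: recall = 1 when the
  ground truth is empty; precision = 1 when neither prediction nor ground
  truth has a voxel (0 if only the prediction is empty); Dice/IoU = 1 when
  both are empty, 0 when exactly one is; FPR = 0 without negatives.
* All rates are computed within the brain mask: including the air
  background would deflate FPR arbitrarily with padding.
* Every metric, the component labelling, the FP counts, the Youden threshold
  and the Wilcoxon p-value are checked against independent brute-force
  oracles (explicit voxel loops, flood fill, exhaustive threshold scans,
  full permutation enumeration) on hundreds of randomised small volumes, and
  Dice = 2·IoU/(1 + IoU) is asserted per case to 1e−12. Note that this
  identity holds per case but *not* for cohort means of Dice and IoU.
* One tempting invariant is intentionally absent: lesion-level FP counts are
  **not** monotone in the probability threshold, because raising the
  threshold can split one predicted component into several. Only voxel-level
  monotonicity (of the binarised mask) and monotonicity in the size limit
  hold, and only those are asserted.

## The packaged experiment

`run_missing_sequence_experiment()` is the end-to-end study: 24 training, 4
validation and 8 test phantoms at 48×48×16 voxels (sizes chosen so the full
two-model experiment runs in a few minutes on one CPU while leaving dozens
of lesions in each cohort), an ILD model (uniform dropout over 0–3 of 4
sequences) and a no-dropout baseline with the same architecture and budget.
Both are evaluated twice on the test cohort: with all sequences, and with
the post-contrast fast-spin-echo sequence unavailable (`1011`) — the
degraded condition in which every surviving sequence still shows the vessel
confounders. The operating threshold is re-selected on the validation set
under each availability pattern, mirroring a deployment that tunes its
operating point on site-matched validation data.

```{r, eval = FALSE}
library(ildseg)
res <- run_missing_sequence_experiment(seed = 1)
res$ild_missing$table       # cohort metrics with one sequence absent
res$wilcoxon                # ILD vs baseline Dice, rank-sum p-value
plot_cohort_roc(res$ild_missing)
```

The reproducible pattern across seeds (asserted by the acceptance tests and
recomputed by `scripts/acceptance.R`): the baseline is marginally better
when every sequence it was trained on is present, but collapses when one is
zeroed — zero-filled inputs are far outside its training distribution —
while the ILD model loses only a few Dice points under the same condition.

## Known limitations

* The phantom task is far easier than clinical metastasis segmentation;
  absolute metric values here say nothing about clinical cohorts.
* Slices are predicted independently; no test-time augmentation, slab
  blending or 3D context beyond the slab.
* The training distribution over dropout patterns is uniform over the number
  dropped, then uniform over subsets — other weightings are configurable but
  unexplored.
* The CPU implementation is intended for desk-scale experiments; clinical
  image sizes (256×256, hundreds of slices, deep backbones) call for a GPU
  framework, to which the mechanism transfers unchanged.
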