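---
title: "DCTR U-Net: model, phantoms and evaluation methodology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{DCTR U-Net: model, phantoms and evaluation methodology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of what it computes and why: the
architecture and its composite blocks, the evaluation metrics and their
pixel-level conventions, the synthetic phantom family, and the design
decisions taken where the architecture description leaves choices open.

## The segmentation model

The package targets binary segmentation of single-channel 2D images —
gross tumor volumes of nasopharyngeal carcinoma on MR slices being the
motivating application. The backbone is a classic U-shaped encoder–decoder;
the contribution of the DCTR family is the per-stage block.

**Dilated convolution.** A convolution with kernel side $K$ and dilation
rate $R$ spaces its taps $R-1$ zeros apart, giving an effective kernel side
$D = K + (K-1)(R-1)$: a 3×3 kernel covers 5×5 at $R=2$ and 7×7 at $R=3$.
This buys receptive field without extra parameters, compensating for the
spatial information lost to pooling. `effective_kernel_size()` implements
the rule; `dilated_conv()` the operation, with "same" zero padding of
$(D-1)/2$ per side so every layer is shape-preserving. The description the
architecture comes from never states the padding scheme, but the skip
connections only align if every block preserves spatial shape, so
shape-preserving padding is forced.

**Transformer layer.** `transformer_block()` is the standard pre-norm block:
$x' = \mathrm{MSA}(\mathrm{LN}(x)) + x$, then
$\mathrm{out} = \mathrm{MLP}(\mathrm{LN}(x')) + x'$, with layer
normalization over the embedding dimension only, per token. Internals not
fixed by the architecture description follow transformer conventions:
8 heads by default, MLP hidden width $4\times$ the embedding, GELU inside
the MLP, no positional encoding, no dropout. The absence of positional
encoding is load-bearing for testing: network output on an all-zero image
must be spatially constant, and token permutations must commute with the
block.

**Transformer inside a spatial block.** Attention over every pixel of a
512×512 map is quadratically infeasible, so inside a block each spatial
position becomes a token (embedding = channel vector) only after the map is
average-pooled to at most a 16×16 token grid (`token_grid`, configurable).
The block adds back the bilinearly upsampled *attention correction* — the
transformer's output minus its input — onto the full-resolution map, rather
than the raw transformer output: the pooled content is already present in
the identity path, and the delta formulation makes the layer an exact
identity when all projection weights are zero, matching the residual
reading of the design. Per-stage head counts are reduced to the largest
divisor of the stage width not exceeding `n_heads`, so desk-scale widths
remain valid.

**The blocks.** All preserve `(batch, channels, height, width)`:

* `dctr_block()` — branch: dilated conv → ReLU → dilated conv → transformer
  layer; identity on the other path; sum, then final ReLU (outputs are
  non-negative).
* `dilated_residual_block()` — branch: dilated conv → ReLU → dilated conv →
  ReLU; plain residual sum, no final activation (outputs may be negative
  where the input is).
* `residual_transformer_block()` — a DCTR block with both convolutions at
  $R = 1$.
* `plain_block()` — two 3×3 conv + ReLU pairs, the baseline U-Net stage
  body.

The dilation rate inside blocks defaults to $R = 2$ for both convolutions
(configurable per network): it enlarges the footprint to $D = 5$, which
still fits the smallest feature map of the default four-stage network,
whereas $R = 3$ would not at desk scale. Whether the two convolutions share
one rate is left open by the source description; they share it here, and
the option to vary it per network is exposed in `network_config()`.

One ambiguity deserves note: the architecture narrative introduces the
transformer "in the last layer of the encoder", yet defines a transformer
layer inside every DCTR block and uses DCTR blocks at every stage. The
package follows the block definition (transformer everywhere) and exposes
`transformer_stages` so a bottleneck-only placement
(`transformer_stages = n_stages + 1`) reproduces the other reading.

## The network

`build_network()` assembles, per encoder stage: 3×3 convolution (channels
change) → BatchNorm → ReLU → variant block (channels unchanged) → 2×2
max-pool, with the skip tap after the block. Channel widths are
`base_channels * c(1, 2, 4, 8)` with `16 * base_channels` at the bottom —
the classic U-Net schedule, scaled by `base_channels` so tests run at width
8 while the full-scale default is 64. The bottom connection module (3×3
conv → BN → ReLU → block) is a single module shared between encoder and
decoder descriptions. Each decoder stage upsamples (bilinear interpolation
+ channel-halving 1×1 convolution by default; a learnable 2×2 stride-2
transposed convolution as an option), concatenates the skip tensor —
"superimposition" is implemented as channel concatenation, because the
stated channel arithmetic (halved on upsampling, restored by the following
convolution) only balances under concatenation — then 3×3 conv → BN → ReLU
→ block. A 1×1 convolution and sigmoid produce the per-pixel foreground
probability; masks are cut at 0.5. The output activation and threshold are
package choices; the source description specifies neither.

Normalization is BatchNorm by default with GroupNorm selectable
(`norm = "group"`), the latter being the standard remedy when memory limits
force small batches. One initialization nuance: before the first training
update, BatchNorm running moments are the uninformative defaults (mean 0,
variance 1), under which deep untrained networks saturate; evaluation-mode
forward passes therefore standardize with batch statistics until the first
update has occurred, and with running moments thereafter. Weights are
He-uniform (convolutions) and Xavier-uniform (attention/MLP projections),
drawn from a seedable stream so `build_network(config, seed)` is
reproducible.

## Metrics

`dice()` reads the overlap formula as set cardinalities,
$2|A\cap B|/(|A|+|B|)$. `assd()` follows its defining symbols: the summands
range over *surface* pixel sets, extracted by `extract_surface()` as
foreground pixels with at least one background 4-neighbor, the image border
counting as background. Distances are between pixel centers, in mm, with
anisotropic `(row_mm, col_mm)` spacing supported and defaulting to 1 mm
(clinical spacing provenance is unknowable without headers, so spacing is
explicit everywhere). None of these pixel-level conventions are stated in
the source description; they were fixed once for determinism and oracle
simplicity, and `assd_bruteforce()` — exhaustive all-pairs distances —
defines correctness for the fast path, an exact anisotropic Euclidean
distance transform (separable lower-envelope parabola passes), to $10^{-9}$.

Empty masks make the metrics undefined (DSC for two empty masks, ASSD
whenever either surface is empty). The package raises distinct errors at
the metric level; `evaluate_case()` converts them to `NA` + an `undefined`
tag, and `evaluate_fold()` excludes such cases from fold means, counts
them, and flags the fold. No silent convention (e.g. DSC 1 for two empty
masks) is invented.

## Phantom cohorts

Clinical NPC data are private; the generator supplies a controllable
stand-in that exercises exactly what the architecture claims to need:
multi-scale context and irregular boundaries. Each slice is a smooth
background (bilinearly upsampled coarse Gaussian field, low-pass scale
`background_smoothness`, default 32 px) plus one star-convex lesion: a mean
radius drawn from `lesion_radius_range` (default 5–20% of the image side,
floored at 3 px) perturbed over angle by a 5-harmonic Fourier series scaled
by `lesion_boundary_roughness` (default 0.15). The lesion interior is
offset by `lesion_contrast` (default +0.4, i.e. a bright lesion; negative
gives dark), a multiplicative low-frequency bias field (default amplitude
0.1) and additive Gaussian noise (default sd 0.05) are applied, and the
image is min–max normalized to [0, 1]. The mask is exactly the lesion
interior. Defaults were chosen once as a plausible MRI-like regime —
visible lesion against a slowly varying background, moderate noise — and
degenerate settings (no roughness, no noise, no bias) reduce the phantom to
an analytically checkable disc.

Cohorts group `slices_per_patient` (default 4; how many clinical slices per
patient entered the original training is unstated) slices per synthetic
patient, with per-patient sub-seeds derived deterministically from the spec
seed and per-slice jitter (1.5% of the side on the center) around
patient-level lesion statistics. Generation is a pure function of
`(n_patients, spec)`. What the phantoms deliberately do **not** model:
multi-modal contrasts, anatomy-specific texture, annotation noise,
inter-observer variability, and multiple or non-star-convex lesions.
Passing tests on phantoms therefore demonstrates that the implementation
trains, discriminates and evaluates correctly — not that clinical accuracy
transfers.

`kfold_split()` shuffles patients under a seed and deals them round-robin,
which makes the "equal folds" property deterministic (300 patients, k = 10
gives exactly 30 per fold) rather than merely expected; assignment is by
patient, so slice-level leakage is impossible by construction.

## Training and experiments

`train_config()` defaults encode the reference protocol: Adam with
$\beta_1 = 0.9$, $\beta_2 = 0.999$ ($\epsilon = 10^{-8}$, unstated and set
to the conventional value), 600 epochs, learning rate $10^{-4}$ stepped to
$10^{-5}$ after 400 epochs (`lr_schedule()` is a right-continuous step with
exactly one switch), batch size 6. The training loss is not stated in the
source description; the package uses (1 − soft-Dice) + binary
cross-entropy by default (`dice_bce`), matching the DSC evaluation target
while keeping early gradients dense, with `dice` and `bce` selectable. The
loss computes its gradient with respect to the pre-sigmoid logits
analytically, avoiding saturated-sigmoid precision loss. Probabilities are
clipped to $[10^{-7}, 1-10^{-7}]$ inside the loss; soft-Dice uses a
$10^{-6}$ smoothing constant. One epoch is one pass over the training
slices with the last partial batch kept; epoch shuffles derive from the
config seed, so runs are reproducible end to end.

`cross_validate()` trains one freshly seeded model per fold (no weight
sharing), evaluates the held-out patients, and reports the fold-1..k +
Ave layout; the Ave column is the mean over fold means. `run_ablation()`
repeats this for `unet`, `unet_dr`, `unet_rt` and `dctr` under identical
fold assignments and identical per-fold initialization seeds, so rows
differ only in block type. The harness records whatever ordering the
phantom cohort produces; no claim is made that phantom orderings reproduce
clinical ones.

## Problem sizes used by the test suite

The suite exercises the full-scale contract once (a 512×512, width-64
forward pass) and otherwise runs desk-scale instances chosen as the
smallest sizes that still exercise every code path: 64×64 images at width
8 for the trainability and ablation checks (4 slices overfit in a few
hundred Adam steps at learning rate $10^{-3}$, a standard overfitting
setting; a 9-patient, 3-fold, 5-epoch ablation), and 32×32 at width 4 for
layer-level tests. Gradient correctness everywhere rests on central
finite-difference checks against the hand-derived backward passes, layer by
layer and through the composed network.

## Known limitations

* 2D only; no volumetric context, in line with per-slice segmentation.
* Single-channel input; multi-modal fusion is out of scope.
* CPU-only and single-threaded apart from BLAS; full-scale 600-epoch
  training is possible but slow — the package's value at scale is
  correctness and auditability, not throughput.
* The ASSD of empty predictions is undefined rather than penalized; folds
  dominated by empty predictions are flagged instead of scored.
* Checkpoints serialize with `saveRDS` plus a JSON config sidecar; they are
  self-describing but not portable to other frameworks.
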