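# dctrunet

Segmentation of tumors in single-channel 2D medical images — the motivating
case is gross-tumor-volume delineation of nasopharyngeal carcinoma (NPC) on
MR slices — with **DCTR U-Net**: a U-shaped encoder–decoder whose per-stage
blocks combine **D**ilated **C**onvolutions, a **T**ransformer layer and
**R**esidual connections. The package is aimed at researchers who want to
train, evaluate and ablate this architecture family on their own cohorts, or
on the built-in MRI-like phantom cohorts when clinical data are unavailable.

Everything is implemented in R: the layers (dilated convolution, batch/group
normalization, max pooling, bilinear and transposed-convolution upsampling,
pre-norm multi-head self-attention) carry hand-derived reverse-mode
gradients backed by compiled Armadillo kernels, trained with Adam.

## The model

A dilated (atrous) convolution with kernel side `K` and dilation rate `R`
has effective kernel side

```
D = K + (K − 1)(R − 1)
```

so a 3×3 kernel covers 5×5 at `R = 2` and 7×7 at `R = 3`, enlarging the
receptive field at constant parameter count. The transformer layer is the
standard pre-norm block

```
x' = MSA(LN(x)) + x
out = MLP(LN(x')) + x'
```

applied to the feature map's spatial positions as tokens (average-pooled to
at most a 16×16 token grid; the attention correction is bilinearly resized
back). The **DCTR block** splits its input into two parallel paths — dilated
conv → ReLU → dilated conv → transformer layer on one, identity on the other
— sums them and applies a final ReLU. Dropping the transformer gives the
**dilated residual (DR) block**; fixing `R = 1` gives the **residual
transformer (RT) block**. Four encoder stages (3×3 conv + BN + ReLU + block
+ 2×2 max-pool, channels 64–128–256–512 by default), a bottom connection
stage (1024 channels), and four decoder stages (channel-halving upsampling,
skip concatenation, 3×3 conv + BN + ReLU + block) map a 512×512×1 image to a
512×512×1 sigmoid probability map.

Evaluation uses the Dice similarity coefficient and the average symmetric
surface distance,

```
DSC  = 2|A ∩ B| / (|A| + |B|)
ASSD = ( Σ_{a∈S_A} d(a, S_B) + Σ_{b∈S_B} d(b, S_A) ) / (|S_A| + |S_B|)
```

with `S_A`, `S_B` the masks' surface pixel sets and `d` the shortest
Euclidean distance in mm (anisotropic pixel spacing honored). Experiments
run as patient-level k-fold cross-validation — patients are shuffled and
dealt round-robin into folds, so 300 patients at `k = 10` give 10 folds of
exactly 30 and no slice-level leakage — and a four-variant ablation harness
(`unet`, `unet_dr`, `unet_rt`, `dctr`) trains all variants under identical
folds and seeds.

## Worked example

Overfit the desk-scale DCTR U-Net (64×64 inputs, base width 8) on four
phantom slices and evaluate it on its own training set:

```r
library(dctrunet)

spec  <- phantom_spec(image_size = 64, slices_per_patient = 4, seed = 11)
cases <- lapply(1:4, function(i) {
  ph <- generate_phantom(spec, seed = 100 + i)
  list(image = ph$image, mask = ph$mask)
})

net <- build_network(network_config("dctr", input_size = 64,
                                    base_channels = 8), seed = 21)
cfg <- train_config(epochs = 60, lr_initial = 1e-3, lr_after = 1e-3,
                    lr_switch_epoch = 0, batch_size = 4, seed = 4)
fit <- train_network(net, cases, cfg, verbose = TRUE)
#> epoch    1  lr 1.0e-03  loss 1.61550  (1.4s)
#> ...
#> epoch   60  lr 1.0e-03  loss 0.06616  (1.1s)

ds <- sapply(cases, function(cs)
  dice(binary_mask(predict_mask(fit$net, cs$image)$masks[[1]]),
       binary_mask(cs$mask)))
round(ds, 3)
#> [1] 0.984 0.988 0.886 0.988
```

The loss (1 − soft-Dice + binary cross-entropy) falls from 1.62 to 0.066 in
60 Adam steps, and the binarized predictions already overlap the phantom
lesions at Dice 0.89–0.99; a few hundred steps reach 1.0 on all four slices.
The metrics follow their textbook fixtures exactly:

```r
A <- matrix(FALSE, 8, 8); A[3:4, 3:4] <- TRUE    # 2x2 square
B <- matrix(FALSE, 8, 8); B[3:4, 3:6] <- TRUE    # 2x4 square containing A
dice(binary_mask(A), binary_mask(B))
#> [1] 0.6666667
a <- matrix(FALSE, 8, 8); a[4, 2] <- TRUE
b <- matrix(FALSE, 8, 8); b[4, 5] <- TRUE        # 3 px apart, 1 mm spacing
assd(binary_mask(a), binary_mask(b))
#> [1] 3
```

The same workflows are scriptable from a shell via `inst/cli/dctrunet`
(subcommands `generate`, `train`, `eval`, `crossval`, `ablate`).

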