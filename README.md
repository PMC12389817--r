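# rhizoseg

Automated segmentation and length quantification of fine roots (< 2 mm
diameter) in field rhizotron and minirhizotron imagery.

Fine roots are thin (1–5 px at typical scan resolutions), low-contrast,
branching structures photographed against heterogeneous soil. `rhizoseg`
implements an improved U-Net for this regime together with the full
supporting pipeline — patch extraction, HSV preprocessing, stochastic
augmentation, training, threshold-swept evaluation, skeleton-based root
length, and agreement statistics against manual measurements — entirely in
R (with the convolution hot loops in C++). Because no tensor framework is
available on this stack, the package ships its own small reverse-mode
autodiff engine over `(C, H, W, N)` arrays.

## The model

The network is a symmetric encoder–decoder U-Net whose DoubleConv blocks
(two 3×3 conv → batch norm → ReLU units) are followed by a Convolutional
Block Attention Module (CBAM). Encoder stages emit 64/128/256/512 channels
with a 1024-channel bottleneck (the test-scale profile uses 8–64/128).
CBAM applies channel attention then spatial attention:

    Mc(F)  = σ( MLP(AvgPool(F)) + MLP(MaxPool(F)) )
    Ms(F′) = σ( f7×7([AvgPool_c(F′); MaxPool_c(F′)]) )
    CBAM(F) = Ms(F′) ⊙ F′,   F′ = Mc(F) ⊙ F

Decoder fusion is either classic skip concatenation or **UpAdd**: the
upsampled decoder feature is channel-aligned by a 1×1 convolution (E), added
element-wise to the skip feature (S), and the sum is modulated by attention
weights computed on `concat(S, E)`:

    U(l) = DoubleConv( (S(l) + E(l)) ⊙ W ),   W from CBAM(concat(S(l), E(l)))

All six ablation variants ({none, SE, CBAM} × {concat, UpAdd}) are reachable
through `unet_config()`.

Training minimizes the hybrid loss

    L = 0.4·L_focal(α = 0.9, γ = 2.5) + 0.4·L_dice + 0.2·L_edge

where the edge term is cross-entropy restricted to a 1-px-dilated Sobel band
around ground-truth boundaries. The optimizer is AdamW (lr 1e-4, weight
decay 1e-4, β = (0.9, 0.999)) with per-epoch cosine annealing; the reported
binarization threshold is the one among 0.1…0.9 that maximizes validation
mIoU.

## Worked example

Generate a synthetic rhizotron dataset, overfit the CPU-scale model, and
evaluate (this is the package's `tiny` profile; ~6 min on one core):

```r
library(rhizoseg)

set <- lapply(1:8, function(i) {
  cfg <- synth_config(size = 64L, n_roots = 3L, contrast = 0.45,
                      noise_scale = 0.06,
                      seed = rhizoseg:::derive_seed(0, i + 1))
  p <- synth_pair(cfg)
  list(x = to_model_input(p$image, 64L), y = binarize_mask(p$mask * 255))
})

model <- unet_init(unet_config(stage_channels = c(8L, 16L, 32L, 64L),
                               reduction_ratio = 4L), seed = 0)
fit <- train_unet(model, set, config = train_config(batch_size = 8L,
                  epochs = 200L, lr0 = 3e-3, seed = 0L, max_steps = 200L))
preds <- unet_predict(fit$model, lapply(set, `[[`, "x"))
sw <- threshold_sweep(preds, lapply(set, `[[`, "y"))
sw$threshold                 # 0.3
round(max(sw$miou), 3)       # 1 (training mIoU; the net memorizes 8 patches)
round(fit$history$train_loss[c(1, 100, 200)], 3)  # 0.507 0.158 0.095
```

The falling loss and a training mIoU ≥ 0.8 confirm that the architecture,
loss gradients, and optimizer work end to end; this is a capacity check on
synthetic data, not a field-accuracy claim.

Agreement between the packaged per-image root-length tables (manual
line-intersect, mm, vs segmentation, px; 10 test images):

```r
tb <- reference_root_lengths()
ag <- length_table_agreement(tb$manual, tb$segmentation)
round(ag$total_length$r, 3)  # 0.719  (p = 0.019)
round(ag$order_3$r, 3)       # 0.880  (p < 0.001; survives Bonferroni, m = 4)
round(ag$order_1$r, 3)       # 0.270  (n.s.)
round(ag$order_2$r, 3)       # -0.106 (n.s.)
```

Third-order roots agree strongly; first/second-order identification is the
known weak point.

## Command line

```sh
Rscript inst/cli/rhizoseg.R synth --n 8 --size 64 --seed 7 --out runs
Rscript inst/cli/rhizoseg.R train --out runs --run-id run --seed 7
Rscript inst/cli/rhizoseg.R evaluate --out runs --run-id run
Rscript inst/cli/rhizoseg.R agree --out runs --run-id run
```

## Layout

- `R/` — autodiff engine, layers, model, losses, trainer, evaluation,
  root traits, synthetic data, pipeline
- `src/conv.cpp` — im2col/col2im packing (BLAS does the arithmetic)
- `inst/extdata/` — packaged reference tables (CSV)
- `vignettes/rhizoseg-methods.Rmd` — model, assumptions, and design notes
- `tests/testthat/` — unit, property, and acceptance suites
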