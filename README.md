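# patchboost

Binary classification of small (96×96) histopathology image patches —
the Patch-Camelyon-style lymph-node-metastasis tiles in which the label
is determined entirely by the **central 32×32 region** — with a "boosted"
EfficientNet-B3-topology convolutional classifier, implemented end to end
in R (C++ convolution kernels, hand-derived backpropagation, no external
deep-learning framework).

The package is aimed at researchers who want to study, at desk scale, the
four boosting strategies for low-resolution medical tiles and the
interplay between them:

| Strategy | What it does |
|---|---|
| **RCC** (random center cropping) | pad 96×96 → 112×112 by 8 px, crop a random 96×96 window back out; every possible window keeps the central 32×32 block intact |
| **RDS** (reduced downsampling scale) | stem convolution stride 2 → 1, so total downsampling drops from 32× to 16× and the final feature map grows from 3×3 to 6×6 |
| **Attention** | squeeze-and-excitation gates: `z_c = mean(U_c)`, `s = σ(W₂ δ(W₁ z))`, channel `c` rescaled by `s_c ∈ (0,1)` |
| **FF** (feature fusion) | outputs of MBConv blocks 4, 7, 17, 25 are pooled (optionally gated) and concatenated with the pooled head features before the linear classifier |

All four are independent flags of `model_config()`, so the full 2⁴
ablation grid can be run with `run_ablation()`. Evaluation reports
ACC, AUC (trapezoidal = Mann–Whitney), SEN, SPE and F-measure.

Because the real ~220k-tile Kaggle dataset is external, the package ships
a seeded synthetic generator that reproduces the data's *structure*
(96×96×3 patches, positive fraction 130908/220025, discriminative signal
strictly inside the central 32×32 window, class-indistinguishable
periphery), so every component is testable offline; see the vignette for
what the generator does and does not emulate.

## Worked example

Train the tiny preset (same 26-block topology, strides and tap indices as
the full-size backbone, reduced widths) on 2,000 synthetic patches:

```r
library(patchboost)

ds <- synthesize_patches(gen_params(n = 2000, seed = 11))
ds
#> <patch_dataset> 2000 patches (1190 positive, 810 negative), 96x96x3

# sanity probe: a threshold classifier on mean center intensity is nearly
# perfect, the same probe on the periphery is at chance
center_signal_probe(ds)
#>    acc_center acc_periphery
#>         0.991         0.523

sp  <- split_dataset(ds, ratio = 0.9, seed = 11)
cfg <- model_config("tiny", rcc = TRUE, ff = TRUE, attention = TRUE)
tc  <- train_config(epochs = 10, batch_size = 32, decay_epochs = integer(0),
                    seed = 11, early_stop_acc = 0.99, verbose = TRUE)
fit <- train(sp$train, sp$val, cfg, tc)
#> epoch 1 lr 0.003 loss 0.6878 val_ACC 0.5950 val_AUC 0.6464
#> epoch 2 lr 0.003 loss 0.6756 val_ACC 0.5950 val_AUC 0.7212
#> epoch 3 lr 0.003 loss 0.6410 val_ACC 0.9600 val_AUC 0.9973
#> epoch 4 lr 0.003 loss 0.1347 val_ACC 1.0000 val_AUC 1.0000

evaluate(fit$model, sp$val)
#> ACC,AUC,SEN,SPE,F
#> 100.00,100.00,100.00,100.00,100.00
```

Reading the output: the model sits at the majority-class rate (0.595, the
positive fraction) for two epochs, then learns the center signal and
separates the validation patches perfectly — the expected behaviour for a
correctly wired pipeline on this deliberately learnable synthetic task
(with `signal_strength = 0` the same run stays at 0.595). The
`evaluate()` row prints the five indicators as percentages in the
conventional ACC, AUC, SEN, SPE, F column order.

Architecture facts are directly inspectable:

```r
m <- build_backbone(model_config("b3", seed = 1))
x <- array(rnorm(96 * 96 * 3), dim = c(96, 96, 3))
dim(forward_features(m, x)$final)[1:2]                         # 3 3
dim(forward_features(reduce_downsampling(m), x)$final)[1:2]    # 6 6
```

A thin CLI (`inst/cli/patchboost`) exposes `generate`, `train`,
`evaluate`, `ablate` and `augment-preview` subcommands over the same
functions.

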