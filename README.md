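# risunet

2.5D liver tumor segmentation in abdominal CT with a Res-Inception-SE U-Net,
implemented as a self-contained R package: the preprocessing pipeline, the
network and its CPU training loop, the evaluation metrics, and a seeded
phantom generator so everything is testable without clinical data.

## The problem and the model

Liver tumors in contrast CT have low contrast against the surrounding
parenchyma, and annotating them slice by slice is slow. Purely 2D networks
ignore the spatial context of neighboring slices; fully 3D networks are
accurate but heavy. The 2.5D compromise feeds a stack of *n* consecutive
slices

X<sub>t</sub> = (I<sub>t−⌊n/2⌋</sub>, …, I<sub>t</sub>, …, I<sub>t+⌊n/2⌋</sub>) ∈ R<sup>H×W×n</sup>

as channels into a 2D encoder–decoder and supervises the center slice only;
slices falling outside the volume are zero-filled. Odd *n* ∈ {1, 3, 5, 7}
keeps the stack symmetric (*n* = 1 recovers the plain 2D model).

The network is a five-level U-Net whose convolution stages are
**Res-Inception-SE blocks**. Each block splits the input into four branches:
a 1×1 convolution (F1), one 3×3 (F2), three serial 3×3s (F3 — a 7×7
receptive field at 3×3 cost), and a pool-plus-convolution branch on F3 (F4).
The branches are concatenated, fused by a 1×1 convolution, reweighted per
channel by squeeze-and-excitation attention (global average pool → C→C/r→C
bottleneck with ReLU/sigmoid), and added to a 1×1 residual projection of the
block input. The default configuration (n = 3, depth 5, channel plan
80–156–312–616–1220, SE reduction 16) has **15.02 M trainable parameters**.

Training minimizes the hybrid objective

L = α·L<sub>Dice</sub> + β·L<sub>BCE</sub>,  α = β = 1 by default,

with Adam (lr 0.003, batch 8, seed 39). Predictions are evaluated per case
with five standard metrics: Dice per case (DPC), volumetric overlap error
(VOE), relative absolute volume difference (RAVD), and the average and
root-mean-square symmetric surface distances (ASSD, RMSD, in mm, via an
exact anisotropic Euclidean distance transform).

All network arithmetic (convolutions, transposed convolutions, pooling,
batch norm, and their backward passes) is implemented in Rcpp/RcppArmadillo;
no external deep-learning framework is required.

## Worked example

Train a small network on synthetic low-contrast phantoms and evaluate it on
held-out cases:

```r
library(risunet)

ds   <- generate_dataset(12, phantom_config(), fractions = c(8, 2, 2), seed = 39)
pcfg <- preprocess_config(crop_size = 64, n_slices = 3)
tr   <- unlist(lapply(ds$splits$train, function(i)
          preprocess_case(ds$cases[[i]]$volume, ds$cases[[i]]$tumor, pcfg)),
        recursive = FALSE)
va   <- unlist(lapply(ds$splits$validation, function(i)
          preprocess_case(ds$cases[[i]]$volume, ds$cases[[i]]$tumor, pcfg)),
        recursive = FALSE)

model <- ris_unet(model_config(n_slices = 3, base_channels = 8), seed = 39)
fit   <- train_risunet(model, tr, va,
                       train_config(max_steps = 200, epochs = 1000, seed = 39))

m <- best_model(fit)
for (i in ds$splits$test) {
  pred <- predict_volume(m, ds$cases[[i]]$volume, pcfg)
  print(evaluate_case(ds$cases[[i]]$tumor, pred, ds$cases[[i]]$volume$spacing,
                      case_id = sprintf("case%d", i)))
}
```

A run of this exact script printed:

```
  case_id       dpc       voe      ravd      assd     rmsd
1   case7 0.7297508 0.4255058 0.1966292 0.8174780 1.129179
2  case11 0.8237854 0.2996301 0.1580595 0.5649293 1.257287
```

i.e. after only 200 optimizer steps the small model reaches a held-out Dice
of 0.73–0.82 on the phantoms, with sub-voxel average surface error
(ASSD < 1 mm at 0.8 mm in-plane spacing). The full-size model is built the
same way with the default `model_config()`:

```r
count_parameters(model_config())   # 15.02  (millions of trainable parameters)
```

A thin command-line wrapper over the same functions is installed at
`inst/cli/risunet.R` (`synth`, `preprocess`, `eval` verbs).

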