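# getnet

A volumetric transformer U-Net for multi-modal MRI brain-tumor
segmentation, implemented and tested entirely in R.

## The problem

Gliomas are segmented on four co-registered MRI modalities (T1, T2, T1ce,
FLAIR) into three *nested* evaluation regions: whole tumor (WT), tumor core
(TC) and enhancing tumor (ET), with WT ⊇ TC ⊇ ET. Pure convolutional U-Nets
see too little context; pure transformer U-Nets see too little local detail.
GETNet combines the two inside a windowed-attention (Swin-style) volumetric
U-Net:

* **GNS** — a *group-normalization shuffle* block after each encoder
  attention stage: channels are split in half, one half passes through a
  `1×1×1 conv → GN+GeLU → 3×3×3 depth-wise conv → GN → 1×1×1 conv → GN+GeLU`
  branch, the halves are concatenated and channel-shuffled
  (`d = shuffle(concat(FS(x), Conv₁×₁×₁(DWC₃×₃×₃(Conv₁×₁×₁(FS(x))))))`);
* **ECSA** — an *enhanced channel self-attention* block, used twice in the
  bottleneck within a pre-norm transformer
  (`Z = y + MLP(LN(y))`, `y = ECSA(LN(x)) + x`). ECSA gates the channels of
  query/key/value paths with squeeze-style sigmoid gates
  `sigmoid(FL(ReLU(FL(AP(x)))))` and computes
  `Y = FL(softmax(Conv₁×₁×₁(DWC₇×₇×₇(K′ ⊙ Q′))) ⊙ V′)`;
* encoder→decoder **K/V bridging**: each decoder stage runs self-attention
  in parallel with cross-attention against the encoder's per-head keys and
  values, fused by the convex combination `(1 − λ)·CA + λ·SA` (λ = 0.5) plus
  a Fourier positional encoding (frequency coefficient 10,000);
* **depth-halving patch merging** (`(C, D, H, W) → (2C, D/2, H/2, W/2)`),
  which strictly reduces the multiply-accumulate count relative to merging
  that keeps the depth axis.

The package also provides BraTS2021-style NIfTI case I/O, the standard
preprocessing (1st/99th-percentile clipping and Z-score over nonzero voxels,
random brain-preserving cropping, rotation/noise/blur/gamma augmentation),
region/label mapping, Dice / HD95 / sensitivity / specificity evaluation,
soft-Dice training with Adam on a built-in reverse-mode autodiff engine, an
analytic MAC counter, and a deterministic synthetic phantom generator so
everything is testable without downloads.

## Worked example

```r
library(getnet)

# 1. a deterministic multi-modal phantom (4 x 32^3, nested WT/TC/ET lesion)
ph <- generate_phantom(phantom_spec(seed = 3))
table(ph$labels)
#>     0     1     2     4
#> 30368   504  1760   136

# 2. preprocessing: percentile clip + Z-score over nonzero voxels, crop
cfg <- toy_config()
pp <- preprocess_case(ph, cfg, seed = 2)

# 3. train the toy network (soft Dice + Adam, lr 1e-4, batch 1)
fit <- train_getnet(cfg, list(pp), steps = 600, lr = 1e-4, seed = 1)
round(fit$history[c(1, 200, 400, 600)], 3)
#> [1] 0.942 0.779 0.554 0.463

# 4. predict and evaluate
pred <- getnet_predict(cfg, fit$weights, pp$volume)
evaluate_case(pred$labels, pp$labels)
#>   region      dice     hd95 sensitivity specificity hd95_defined
#> 1     WT 0.8426581 2.236068   0.7687500   0.9955875         TRUE
#> 2     TC 0.7920354 3.000000   0.8390625   0.9944285         TRUE
#> 3     ET 0.3578947 4.532878   0.6250000   0.9922162         TRUE

# 5. analytic multiply-accumulate comparison of the merging variants
c(halving = count_macs(cfg)$total,
  fixed   = count_macs(getnet_config(depth_halving = FALSE))$total)
#> halving   fixed
#> 7654400 9808896
```

The loss trajectory shows the network overfitting a single phantom under the
published recipe (Adam, learning rate 1e-4, batch size 1); after 600 steps
the thresholded prediction recovers the whole tumor at Dice 0.84 with a
2.2 mm HD95. The small enhancing-tumor ellipsoid (136 voxels) converges last
— see the methods vignette for the optimization analysis. The MAC totals
show the depth-halving design cutting compute by ~22% on the toy profile,
the direction of effect reported for the full-scale model.

A command-line wrapper (`inst/cli/getnet.R`) exposes the same pipeline as
`synth`, `train`, `predict` and `evaluate` subcommands:

```sh
Rscript inst/cli/getnet.R synth --n 2 --seed 1 --out phantoms
Rscript inst/cli/getnet.R train --data phantoms --out ck.rds --steps 200
Rscript inst/cli/getnet.R predict --checkpoint ck.rds \
    --case phantoms/PHANTOM_00001 --out pred/PHANTOM_00001.nii.gz
Rscript inst/cli/getnet.R evaluate --pred pred --truth phantoms
```

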