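# bmdnet

Estimation of lumbar bone mineral density (BMD, g/cm²) from single-energy
anteroposterior radiographs, for researchers studying opportunistic
osteoporosis screening without dual-energy X-ray absorptiometry (DXA)
hardware. The package implements the full hybrid pipeline as tested,
desk-scale R code and exercises it end-to-end on synthetic phantom
radiographs with known ground truth, because paired
radiograph/soft-tissue/BMD clinical data cannot be shared or, for the
soft-tissue component, even acquired.

The method has three stages:

1. **Learned soft-tissue subtraction.** A U-Net (two 3×3 convolutions +
   ReLU and 2×2 max-pooling per encoder level, mirrored decoder with skip
   connections, 1×1 output head) is trained with plain stochastic gradient
   descent, θ_{t+1} = θ_t − η ∇J(θ_t), under a mean-squared-error loss to
   predict the soft-tissue image; subtracting it from the radiograph leaves
   a bone-dominant image — a single-energy, learned analogue of dual-energy
   subtraction.
2. **Regional grayscale features.** The vertebral ROI is partitioned into
   five regions (upper, lower, left, central, right). Per region, pixels
   are clipped to three intervals around the region mean μ and standard
   deviation σ — [μ−σ, μ+1.96σ], [μ±1.96σ], [μ−1.96σ, μ+σ] — and averaged.
   The 15 clipped means, 5 raw means, the whole-ROI mean, body weight (kg)
   and vertebral area (cm²) form a 23-element feature vector.
3. **Bounded neural regression.** A 23–32–16–8–1 feed-forward network with
   ReLU hidden layers and output activation f(x) = 0.55·tanh(x) + 0.85,
   whose open range (0.3, 1.4) g/cm² makes every prediction biologically
   plausible by construction. Training uses an 80/20 split (1:4
   validation:training) and early stopping on validation loss.

Evaluation reports Pearson r, r² and MAE, plus a paired comparison of the
pipeline with and without the subtraction stage under identical seeds —
the central claim being that learned soft-tissue suppression improves BMD
prediction.

All of it — the phantom generator, the U-Net with hand-derived backprop,
the feature extractor and the regressor — is implemented in the package
(no deep-learning framework underneath) and verified against numerical
gradients and independent oracles in the test suite.

## Worked example

```r
library(bmdnet)

## a desk-scale experiment: 300 phantoms at 64x64, one global seed
cfg <- run_config(n = 300, image_size = 64, seed = 1)
result <- run_pipeline(cfg)        # ~6 min on one CPU
tidy(result)
#> # A tibble: 4 × 6
#>   arm        subset     pearson_r r_squared    mae     n
#>   <chr>      <chr>          <dbl>     <dbl>  <dbl> <int>
#> 1 raw        train          0.944     0.892 0.0740   240
#> 2 raw        validation     0.935     0.874 0.0889    60
#> 3 subtracted train          0.947     0.896 0.0724   240
#> 4 subtracted validation     0.941     0.886 0.0848    60

glance(result)
#> # A tibble: 1 × 3
#>   delta_r delta_mae     n
#>     <dbl>     <dbl> <int>
#> 1 0.00667  -0.00407    60
```

Read: on held-out phantoms the subtracted arm tracks true density with
r ≈ 0.94 and a mean absolute error of ≈ 0.085 g/cm². Running the identical
regressor on the raw (unsubtracted) radiographs gives lower correlation
and higher error; the paired validation delta (Δr > 0, ΔMAE < 0) is the
package's reproduction of the soft-tissue-suppression benefit. On
phantoms the margin is small — the synthetic backgrounds are smoother
than real abdominal anatomy and the weight/area covariates alone carry
much of the signal — so it is the sign, not the clinical magnitude, that
is reproduced. Individual
stages are available as ordinary functions (`synthesize_cohort()`,
`train_unet()`, `predict_soft_tissue()`, `subtract_soft_tissue()`,
`extract_feature_table()`, `train_ann()`, `predict_bmd()`), all returning
tibbles or plain matrices; `autoplot()` methods show phantoms, training
curves and true-versus-predicted scatter.

A thin command-line front end wraps the same functions:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/bmdnet.R", package="bmdnet"))')" \
    run-all --n 300 --image-size 64 --seed 1 --out results/run1
```

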