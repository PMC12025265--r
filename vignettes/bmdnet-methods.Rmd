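---
title: "Methods: phantom-based BMD estimation with learned soft-tissue subtraction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phantom-based BMD estimation with learned soft-tissue subtraction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Areal bone mineral density (BMD, g/cm²) of the lumbar vertebrae is the
standard quantity for osteoporosis assessment, normally measured by
dual-energy X-ray absorptiometry (DXA). A single-energy anteroposterior
radiograph also carries density information — the vertebral body's mean
attenuation and trabecular texture both track BMD — but the signal is
confounded by the soft tissue the beam traverses. `bmdnet` implements a
hybrid estimation pipeline:

1. a **U-Net** is trained to predict the soft-tissue component of a
   radiograph; subtracting it leaves a bone-dominant image (the learned,
   single-energy analogue of dual-energy subtraction);
2. the vertebral region of interest (ROI) of the bone image is partitioned
   into five regions whose threshold-clipped grayscale means, together with
   body weight and vertebral area, form a **23-element feature vector**;
3. a small feed-forward network with a **bounded tanh output** maps the
   features to BMD.

Because paired radiograph/soft-tissue images cannot be acquired clinically,
training and evaluation run entirely on **synthetic phantom radiographs**
with known decomposition and known true BMD. The phantom generator is
first-class, tested code: every downstream claim the package's test suite
makes is a claim about this generator's output distribution.

## The phantom generator

A phantom sample is built additively,

$$\mathrm{input} = \mathrm{clamp}(\mathrm{soft} + \mathrm{bone},\, 0,\, 1)
  + \varepsilon, \qquad \varepsilon \sim N(0, \sigma_\text{noise}^2),$$

which is exactly the physical premise that justifies recovering the bone
image by subtraction. All intensities are floats in [0, 1] internally
(8-bit PNG or 16-bit TIFF on disk), so quantization never interacts with
the threshold arithmetic during tests.

* **Soft tissue** — a sum of three band-limited Gaussian noise octaves plus
  a random lateral gradient, scaled per image to a base attenuation level
  drawn from [0.05, 0.22] and an amplitude from [0.18, 0.33]: smooth,
  inhomogeneous, organ-overlap-like backgrounds whose overall brightness
  differs between images the way soft-tissue thickness differs between
  patients. The per-image level is what makes raw-image prediction
  genuinely confounded — averaging the ROI cannot cancel it — and it is
  exactly the quantity the U-Net can recover from the pixels around the
  vertebra.
* **Vertebra** — a rounded rectangle (half-height 0.28·size, half-width
  0.20·size) centred in the frame, with multi-scale zero-mean texture
  (sd 0.04) emulating trabecular structure. Mean intensity inside the mask
  is affine in true density:
  $$\mu_\text{mask} = 0.08 + 0.38 \cdot \mathrm{BMD},$$
  chosen so that the darkest templates (BMD 0.35) stay clearly above zero
  and the brightest (BMD 1.35), added to the brightest soft tissue, only
  rarely saturates.
* **Four-fold jitter and compositing** — four copies of the template with
  contrast ∈ [0.9, 1.1], brightness ∈ [−0.03, 0.03] and tilt ∈ [−5°, 5°]
  are merged by their pixel-wise mean. The merge operator was genuinely
  open; the mean keeps intensities in range with no renormalization, which
  is why it was chosen over sum or max.
* **Augmentation** — a lossless quarter-turn rotation and axis flip,
  applied to image and mask alike so the ROI bounding box remains exact.
* **Covariates** — weight = 40 + 25·BMD + N(0, 4²) kg and
  area = 10 + 4·BMD + N(0, 1²) cm², a linear-Gaussian stand-in for the
  reported positive correlation of both quantities with BMD. With BMD
  uniform on [0.35, 1.35] the model implies corr(weight, BMD) ≈ 0.87 and
  corr(area, BMD) ≈ 0.76, which the test suite verifies empirically.
* **True BMD** — uniform on [0.35, 1.35] g/cm², the biologically plausible
  lumbar band, matching the open range (0.3, 1.4) of the regressor's
  output activation.

What the phantoms do **not** emulate: physically accurate attenuation
(no Beer–Lambert integration, no scatter, no beam hardening), anatomical
shape variation, adjacent structures (ribs, pelvis, bowel gas), and
detector physics. Passing tests therefore demonstrate that the pipeline's
machinery — subtraction, features, regression — recovers a known density
signal under controlled confounding; they are not clinical validation.

## The U-Net and its training

The network follows the classic encoder–decoder shape: each of `depth`
(default 3) encoder levels applies two 3×3 convolutions with ReLU followed
by 2×2 max pooling; a two-convolution bottleneck sits below; the decoder
mirrors the encoder using nearest-neighbour upsampling followed by a 3×3
convolution (cheaper and artifact-free at these sizes compared with
transposed convolution), a channel-concatenating skip connection from the
matching encoder level, and two further 3×3 convolutions; a 1×1
convolution produces the single-channel soft-tissue estimate. Widths start
at `base_channels` (default 16) and double per level. Everything —
im2col convolutions routed through BLAS, the backward pass, the training
loop — is implemented in the package and verified against numerical
gradients in the test suite.

Two architectural details matter at desk scale. The output head carries a
**global residual connection** — the network predicts the soft image as
`input + delta` — the standard construction for subtraction and denoising
networks, so the identity is the starting point rather than something
plain SGD must spend its budget rediscovering. And the 1×1 head (like the
regressor's output layer) is **zero-initialized**: with a random head the
initial output sits far outside the data range where the clamped target
band (or a saturated tanh, for the regressor) provides little usable
gradient.

Optimization is **plain stochastic gradient descent**,
$\theta_{t+1} = \theta_t - \eta \nabla_\theta J(\theta_t)$, on the mean
squared error between predicted and true soft-tissue images, over seeded
shuffled mini-batches. No momentum, no weight decay, no schedule. The
reference protocol uses batch size 2: with a few dozen training images,
larger batches leave plain SGD too few updates per epoch to converge in a
desk-scale budget, and halving the batch doubles the update count at
identical cost.
The default learning rate is η = 0.05 (0.08 in the reference protocol,
where the zero-initialized head keeps the early steps stable): at desk
scale these rates converge several times faster than 0.01 and remain
stable, whereas 0.1 from a random head diverges; the rate is
configurable. The training loss acts on the network's linear
output; the [0, 1] clamp is applied only at prediction time. (Clamping
inside the loss zeroes the gradient wherever the output starts outside
[0, 1], which can freeze the whole network at initialization — the linear
loss keeps subtraction linear near the data range and gradients alive
everywhere.)

Soft-tissue prediction is a per-pixel task: a few dozen 64×64 images
already supply hundreds of thousands of supervised pixels. The reference
protocol therefore fits the U-Net on a 48-image subset of the training
split for 30 epochs; the full cohort is used for the regressor.

## Features

The ROI is the vertebra's known bounding box (phantoms track it through
augmentation exactly; for external images a manual ROI rectangle is read
from the manifest). A 3×3 grid with cell boundaries at `floor(i·n/3)`
partitions the ROI into **upper** (whole top row of cells), **lower**
(whole bottom row), **left**, **central**, **right** (middle-row cells) —
the corners are absorbed into the top and bottom rows, giving a disjoint,
exhaustive partition. Per region, with mean μ and standard deviation σ of
the grayscale values, three clipping intervals are applied:

| Set | interval |
|-----|----------------------|
| 1 | [μ − σ, μ + 1.96 σ] |
| 2 | [μ − 1.96 σ, μ + 1.96 σ] |
| 3 | [μ − 1.96 σ, μ + σ] |

Values below A1 are set to A1 and above A2 to A2 (idempotent, verified
against a per-pixel oracle). The feature vector is, in fixed order: the 15
clipped region means (regions upper, lower, left, central, right × sets
1–3, region-major), the 5 raw region means, the whole-ROI mean, weight and
area — 23 inputs. μ and σ are computed per region, before clipping, on the
subtracted bone image.

## The regressor

A 23–32–16–8–1 feed-forward network: ReLU hidden activations and the
bounded output
$$f(x) = 0.55 \tanh(x) + 0.85 \in (0.3,\ 1.4),$$
so predictions can never leave the plausible BMD band regardless of
training state. The funnel widths are a conventional choice; only the
count of hidden layers (three) is structural. Features are z-score
standardized with training-set statistics only (stored in the model and
reapplied at prediction); targets must lie inside the activation's open
range. Training is plain mini-batch SGD (η = 0.005, batch 16) with early
stopping: when the best validation MSE fails to improve by more than 1e-5
for 20 consecutive epochs, training halts and the best-validation
parameters are restored. The data split is a seeded shuffle with 80%
training / 20% validation (ties in the rounding go to training), i.e. a
1:4 validation:training ratio — 240/60 at the reference cohort size of
300.

## Evaluation and the paired comparison

`eval_report()` gives Pearson r, r² and the mean absolute error; r and r²
are always reported side by side and never conflated. The central
qualitative claim — that learned soft-tissue subtraction improves BMD
prediction — is tested by `compare_pipelines()`: the identical cohort,
split and regressor seed are run once on subtracted bone images and once
on raw radiographs, and the validation deltas (Δr, ΔMAE) are reported.
On phantoms the raw arm is far less handicapped than on clinical images —
the synthetic soft tissue is smoother and weaker than real abdominal
anatomy, and the weight/area covariates alone carry r ≈ 0.9 — so the
expected improvement is real but small; the package asserts its sign, not
its clinical magnitude.

## Numerical choices and degenerate inputs

* Seeds: one global seed derives every stage seed (hash-style affine map
  modulo a prime below 2³¹); all randomness flows through a
  save/restore-RNG helper, so a run is bit-reproducible and never
  disturbs the caller's RNG stream.
* σ = 0 regions (constant grayscale) give A1 = A2 = μ and clipping leaves
  the region unchanged; the standardizer replaces zero-variance feature
  sds by 1.
* Max-pool gradients use first-wins argmax so each gradient lands on
  exactly one input pixel even under ties.
* Arbitrary-angle rotation is bilinear about the image centre with zero
  fill; quarter-turn augmentation uses exact index remapping and is
  bit-losslessly invertible.
* The problem sizes of the reference protocol — cohorts of 300 samples at
  64×64 px, a 48-image U-Net training subset, 30 U-Net epochs — are the
  package's desk-scale defaults; 256×256 and wider networks are
  configuration changes, not code changes.

## Known limitations

* Phantom realism is deliberately limited (see above); clinical numbers
  from the literature are not reproducible from synthetic data and are not
  claimed.
* No automatic vertebra localization: the ROI comes from the phantom
  ground truth or a user-supplied rectangle.
* Plain SGD is part of the method's definition here; adaptive optimizers
  would train faster but are out of scope.
* The feature composition (15 clipped + 5 raw + 1 global + 2 covariates)
  is one consistent reading of a 23-input layer; per-region σ or other
  statistics would be an alternative composition.
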