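---
title: "Conditional WGAN-GP fundus synthesis: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Conditional WGAN-GP fundus synthesis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's own account of the science it implements:
the generative model and its losses, the stand-in networks, the synthetic
data the pipeline is validated on, the numerical choices, and what the
passing test suite does and does not establish about real data.

## The model

The package synthesizes retinal fundus images with a conditional
Wasserstein GAN with gradient penalty. The generator
$G_\theta(y, D(x), z)$ receives

* $y$ — a binary vessel-segmentation mask (physiological conditioning),
* $D(x)$ — two binary lesion-descriptor maps at a fine and a coarse scale
  (pathological conditioning), and
* $z \in \mathbb{R}^Z$ — a noise vector (diversity),

and emits an RGB image $\hat{x} \in [0,1]^{W \times H \times 3}$. A critic
$D_\gamma(x, y)$ scores (image, mask) pairs with an unbounded linear
output. The critic maximizes the Wasserstein loss
$L_W = D_\gamma(x,y) - D_\gamma(G_\theta(y,z), y)$ under the two-sided
gradient penalty $E[(\lVert \nabla_{\tilde{x}} D_\gamma(\tilde{x},y)
\rVert_2 - 1)^2]$ evaluated at uniform interpolates
$\tilde{x} = u x + (1-u)\hat{x}$; the generator minimizes

$$L_G = -D_\gamma(\hat{x}, y) + w_p L_{percept} + w_s L_{severity}.$$

The two style-transfer terms tie the synthetic image to its source: the
severity loss is the absolute difference of a DR grader's scalar estimates,
$|DR(x) - DR(\hat{x})|$, and the perceptual loss is the element-averaged
squared difference of feature maps at a chosen layer $\lambda$ of a fixed
feature network. Both norms are deliberate design choices — the severity
scale is ordinal, so a scalar regression difference is the natural reading,
and the squared feature distance is the common perceptual-loss convention;
both functions accept user-supplied networks so other conventions can be
plugged in.

## Lesion descriptors from grader saliency

$D(x)$ is distilled from the grader by backpropagation: the scalar grade
estimate is differentiated with respect to the input pixels, and the
channel-summed absolute gradient is the lesion saliency. The saliency
operator is the bare input gradient — the simplest operator consistent
with "backpropagate the lesion activations", and the only one that is
directly testable against finite differences. The saliency map is smoothed
with discrete Gaussian kernels (truncated at $4\sigma$, renormalized,
reflect padding) at $\sigma_{fine} = 1$ px and $\sigma_{coarse} = 4$ px,
and each smoothed map is binarized at its own empirical $1-q$ quantile
(default $q = 0.02$, i.e. the top 2 % of in-view saliency) computed over
field-of-view pixels only, with threshold ties included. Quantile
thresholds are scale-invariant to the saliency magnitude, which any fixed
threshold is not; the restriction to the field of view avoids the
structurally black aperture corners diluting the quantile. The two tensors
are two *scales* at equal resolution, not two resolutions — the simplest
reading consistent with a two-channel conditioning input.

## The stand-in grader

The external DR detector and the pretrained perceptual network that a
full-scale deployment would use are both replaced by one small
convolutional regressor trained on the synthetic data; its roles:

1. severity scorer $DR(\cdot)$ for the severity loss,
2. saliency source for lesion extraction,
3. feature extractor for the perceptual loss (default layer `stage2`), and
4. pooled-feature embedder for FID.

Its architecture has two branches feeding one linear head:

* a *trunk* of 3×3 stride-2 conv stages (widths 16-32-48, ReLU) — the
  named feature layers with cumulative stride $2^k$;
* a *lesion-evidence branch* at full resolution: one 3×3 context layer
  (16 channels, leaky ReLU 0.1), 1×1 conv layers (8 channels), and a
  2-channel output head whose activation is almost one-sided (leaky slope
  0.01 below zero, bias initialized at +0.05).

The head regresses the grade from the trunk's global-average-pooled
features together with the two summed evidence areas. The evidence branch
mirrors how severity grading actually works — detect lesions pointwise,
integrate their extent — and turns the head's job into a near-linear
calibration from lesion area to grade. During training the branch is
supervised by the dataset's lesion masks with lesion pixels upweighted
(weight 12) to counter the roughly 2 % lesion-pixel class imbalance, and
the grade loss reaches the branch only through the head (a stop-gradient
at the pooled areas): letting the noisy early grade gradients into the
detector weights measurably destabilizes them. Both choices are visible,
documented training details of the stand-in, not claims about the original
detector. The nearly-one-sided output matters: a hard terminal ReLU can
silence an evidence channel permanently on unlucky seeds, while a signed
linear output lets negative background noise cancel genuine lesion area in
the pooled sums; slope 0.01 with a positive bias start avoids both failure
modes.

Inputs are centered ($x - 0.5$) inside the model; training uses Adam
(learning rate 5e-3, batch 8) under random orientation augmentation
(flips/transposition — severity is orientation-invariant). Training is a
seeded, fully reproducible function of (data, epochs, seed). The held-out
metric is the *within-one accuracy* — the fraction of evaluation samples
predicted within one grade — the natural tolerance for an ordinal 0–4
scale.

## The synthetic fundus generator

The procedural generator emulates the *structure* of graded DR photograph
collections so that every downstream stage is testable without downloads:
a circular field of view (radius 0.48 of the side), a bright optic disc
near the nasal edge, a vessel tree grown from the disc by recursive
branching random walks (width decaying 0.72 per branch depth) rasterized
both into the image and into the paired ground-truth mask, and elliptical
lesions — dark microaneurysm-like and bright exudate-like, split into a
fine mask (rasterized area ≤ 9 px) and a coarse mask — placed uniformly
inside the field of view without overlapping vessels, disc or each other.
Additive Gaussian pixel noise (sd 0.02) is applied inside the field of view
and the image clipped to $[0,1]$; outside the aperture stays structurally
black, as in real fundus photography.

The severity grade is drawn uniformly from 0–4 and the lesion count
uniformly from $[4g, 4g+3]$, so the grade is exactly recoverable as
$\lfloor count/4 \rfloor$ — a deliberately learnable grading rule that
gives the stand-in grader a well-posed target; it is a test convenience,
not a claim about clinical grading. Two rendering choices serve the same
purpose and are worth stating: lesion colors occupy bands separated from
both the vignetted background (red ≥ 0.54 anywhere in view) and the
vessels (red ≈ 0.32) — dark lesions at (0.42, 0.15, 0.08), bright at
(0.97, 0.88, 0.45) — and the two lesion size classes have narrow radius
jitter, so per-class pixel area tracks the count closely. Without the
color separation the grade is genuinely ambiguous from pixels (rim
background approaches the lesion color), which defeats the module's stated
purpose of providing a learnable severity signal.

What the generator does *not* emulate: photometric realism, camera optics,
vessel tortuosity statistics, lesion texture, inter-patient variation, or
any real dataset's intensity distribution. Passing tests therefore
establish that the pipeline's mechanics are correct (losses, gradients,
conditioning, training dynamics, metrics) — not that the synthesis quality
transfers to real fundus photographs.

## Resampling kernels

The comparison axis of the method is the resampling kernel, applied in two
places: image preprocessing to a uniform side, and every decoder
upsampling step of the generator — the only reading under which the
kernel choice can influence generated-image metrics. Kernels follow the
conventional definitions: `nearest` (round-half-up toward the larger
index), `bilinear` (tent, support 1), `bicubic` (Keys, $a=-0.5$),
`mitchell` (Mitchell–Netravali, $B=C=1/3$), `lanczos5` (sinc·sinc, support
5). Coordinates map with half-pixel centers ($s = (d+0.5)\,n_{in}/n_{out}
- 0.5$), edges clamp, per-destination weights renormalize to 1, and
antialiasing stretches the kernel by the inverse scale when downscaling
(upscaling is unaffected; `nearest` ignores the flag, matching the common
library convention its name is drawn from). Cubic and Lanczos overshoot is
clipped to $[0,1]$ at the API surface; the generator's internal upsampling
layers operate unclipped since feature maps are not pixel-valued.

## Architectures and optimization

Neither network architecture is prescribed by the problem, so the package
uses the smallest family that trains on one CPU while honoring the
conditioning interface. The generator is a 4-stage stride-2 conv encoder
over the 3-channel condition stack (widths 4-8-16-32 at the default
`base = 4`), noise injected at the 4×4 bottleneck by a linear projection,
and a 4-stage decoder of resample-upsample + conv with skip connections
from the encoder stages and from the raw condition stack. The two
full-resolution decoder convolutions are 1×1: spatial structure at the
output scale then comes from the resampling kernel itself, which keeps the
method-variant axis visible in the output and keeps full-resolution
compute affordable; the last 3×3 spatial convolution sits at half
resolution. The critic is a 4-stage stride-2 conv stack (widths 4-8-16-32,
leaky ReLU 0.2) on the channel-concatenated (image, mask) pair with a
linear scalar head — the critic deliberately does not see $D(x)$, since
the Wasserstein loss is defined on (image, mask) pairs only.

Optimization follows the usual WGAN-GP structure — Adam with momentum
pair (0, 0.9), five critic updates per generator update, loss weights
$w_p = w_s = 1$ by default, $Z = 128$ — with three deliberate desk-scale
adaptations of the canonical recipe, each addressing a failure mode that
the 500-step horizon makes visible:

* *Learning rates 2e-3 (generator) and `lr/4` (critic)* instead of the
  canonical 1e-4 for both. 1e-4 is tuned for runs of $10^5$ steps; at 500
  steps it leaves the generator essentially at its initialization while
  the critic sharpens, so the interpolate gradient norm drifts away from
  1 and the synthesized distribution never moves. The deliberately slower
  critic keeps the two networks in balance.
* *Penalty coefficient $\lambda_{gp} = 100$* in the training default
  (the bare loss functions keep the conventional 10). The critic's
  stationary gradient norm balances the Wasserstein term's parameter
  gradient against the penalty's; with a small critic the former is
  relatively large, and at $\lambda_{gp}=10$ the norm equilibrates near
  1.9 rather than calibrating toward 1. At 100 the equilibrium sits at
  roughly 1.02–1.1 across seeds without measurably changing the
  synthesis quality (pixel MSE within a few percent).
* *Conservative critic initialization* (He weights scaled by 0.25): the
  critic starts as a nearly flat scorer whose interpolate gradient norm
  sits well below 1, and the penalty calibrates it upward — the canonical
  picture of gradient-penalty training. A full-scale He initialization
  already starts with $O(1)$ gradients, so the first training phase would
  begin, by accident of initialization, closer to 1 than the equilibrium
  it converges to. Batches are drawn without replacement per epoch from a
seeded stream; every logged number is a deterministic function of (data,
grader, config), checkpoints capture the random-stream position so resumed
runs reproduce unbroken ones exactly, and a non-finite loss aborts with
the last good checkpoint attached rather than skipping silently. The
gradient penalty's parameter gradient is computed exactly by a
forward-over-reverse pass (for piecewise-linear critics the input-gradient
map is linear given the activation masks, so its parameter derivative is a
second reverse pass over tangent activations); it is verified against
finite differences in the test suite. The lesion descriptors and style
targets (severity scores, perceptual features) of the real images are
computed once per training pool with the frozen grader and cached — they
are constants of the optimization.

## Metrics

FID is computed as $\lVert \mu_r - \mu_g \rVert^2 + \mathrm{Tr}(\Sigma_r +
\Sigma_g - 2(\Sigma_r \Sigma_g)^{1/2})$ on Gaussian fits (sample mean,
$n-1$ covariance) of embedded features. The matrix square root uses the
symmetrized product $\Sigma_r^{1/2} \Sigma_g \Sigma_r^{1/2}$ and
eigendecomposition with negative eigenvalues clipped at $-10^{-10}$
(beyond that tolerance the input is rejected as non-PSD) — this keeps the
result real and the trace term symmetric. The default embedder is the
stand-in grader's pooled `stage2` features; FID values are comparable only
within one embedder, and reports record which was used. MSE is the plain
pixel mean on the $[0,1]$ float scale, before any 8-bit quantization. SSIM
uses the standard constants $C_1 = (0.01 L)^2$, $C_2 = (0.03 L)^2$ with
dynamic range $L = 1$ and an 11×11 Gaussian window ($\sigma = 1.5$) over
valid positions, on grayscale (channel-mean) images; a `global` mode
evaluates the formula once with whole-image moments for direct formula
checks. Evaluation pairs real and generated images per sample for MSE and
SSIM, pools feature statistics for FID, and repeats generation with fresh
noise seeds to report dispersion — repeats vary the noise only, not the
trained weights.

## Problem sizes and limitations

The shipped defaults are desk-scale study conditions: 64×64 images,
500-sample datasets (400 train / 100 held out for the grader), a 200-image
adversarial training pool, 500 generator steps with five critic updates
each, and three replicate seeds where stochastic behavior is asserted.
These sizes exercise every code path and the qualitative training dynamics
(gradient-norm calibration toward 1, FID improving over initialization)
while staying reproducible on a single CPU. Known limitations: the
synthetic images are cartoons of fundus anatomy, the stand-in grader is
not a clinical DR detector, 64-pixel resolution cannot express fine lesion
texture, and FID under a toy embedder is not comparable to values computed
under an ImageNet Inception network. The package treats all external
networks as plug-in points precisely so that real-data deployments can
swap them in without touching the pipeline.
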