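---
title: "Lightweight 3D CNNs for volumetric classification: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lightweight 3D CNNs for volumetric classification: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(slim3d)
```

## The problem

Volumetric classification of structural brain MRI — for example separating
scans with dementia-related atrophy from cognitively normal ones — is usually
attacked with 3D convolutional networks. Full 3D CNNs are accurate but heavy:
tens of millions of parameters and hundreds of GFLOPs per scan, which rules
out deployment on clinical workstations or edge devices. `slim3d` implements
a family of techniques that compress a 3D CNN by roughly two orders of
magnitude while keeping the classification machinery intact, and packages
them with a profiler, a statistics harness and interpretability tools so the
whole pipeline can be studied quantitatively on synthetic data.

## The architecture

A model is a sequential stack:

1. **Stem.** A 1×1×1 convolution maps the single input channel to
   `stem_channels` (default 24) feature channels — cheap channel expansion
   before any spatial filtering.
2. **Depthwise-separable stages.** Each stage factorizes a full 3D
   convolution into a per-channel spatial convolution (`k³ · c_in` weights)
   followed by a 1×1×1 pointwise mixing (`c_in · c_out` weights), replacing
   `k³ · c_in · c_out`. Every convolution is followed by batch
   normalization and ReLU; convolution biases are disabled because the batch
   norm shift absorbs them. Early stages run at stride 2 for downsampling;
   the final two stages run at stride 1 with **dilated** depthwise kernels
   (rates 2 and 4), which widens the receptive field at zero parameter cost.
3. **Multi-scale fusion (LMF).** At one intermediate stage, parallel
   depthwise-separable branches at kernel sizes 3³ and 5³ extract features
   at two receptive fields. Their channel-concatenation is globally
   average-pooled to a descriptor `z`, a two-layer gate
   `softmax(W2 · ReLU(W1 z + b1) + b2)` produces one weight per scale, and
   the output is the convex combination `Σ αᵢ Fᵢ`. The gate hidden width is
   `S·C/4` (floored, minimum 4). Because `Σ αᵢ = 1`, identical branches make
   the block gate-independent — a property the tests exploit.
4. **Parameter-free attention (ILS).** Per channel, the feature map is
   centered by its spatial mean μ and scaled by `0.5 / (φ² + λ)` with φ² the
   *population spatial variance* and `λ = 1e-4` a zero-division guard, then
   shifted by 0.5; the sigmoid of this normalized map is an attention mask
   multiplying the input. For a constant channel the mask is exactly
   `sigmoid(0.5) ≈ 0.6225`. Reading φ² as the variance (rather than the
   sigmoid that the same symbol denotes elsewhere) is the only
   dimensionally coherent interpretation, and is fixed by the worked
   examples in the test suite.
5. **Head.** Global average pooling and a fully connected layer to the
   class scores; probabilities are softmax-normalized and argmax ties break
   toward the lower class index.

The default full-size ladder is `round(1.95 × (24, 64, 128, 256, 512))`
channels. Only the stem width (24), the kernel set {3, 5} and "dilation on
the last two stages" are fixed by the reference design; the stage count and
widths are a calibrated reconstruction. The multiplier 1.95 was chosen once
by `calibrate_width_multiplier()`, a grid search matching the unpruned
parameter count to the published 0.92 M budget (919,305 parameters, 0.08%
off); it was not revisited afterwards.

## Training

The loss is label-smoothed cross-entropy (`ε = 0.1`) plus an L1 penalty
`λ Σ |γ|` (`λ = 1e-4`) on the scales of every prunable batch-norm layer —
the penalty drives unimportant channel scales toward zero so pruning can
find them. The optimizer is SGD with momentum 0.9 and weight decay 1e-4;
gradients are accumulated over micro-batches of 4 to an effective batch of
16. The learning rate (default 0.005) is multiplied by 0.1 when the
*training* loss fails to improve by a relative 1e-4 for 10 consecutive
epochs. Training-set augmentation adds Gaussian noise (sd 0.01 on the [0,1]
scale) and a gamma-correction exponent drawn uniformly from [0.8, 1.25] —
mild perturbations chosen because strong spatial transformations distort
volumetric structure. All backward passes are hand-derived and checked
against central finite differences in the test suite.

At desk scale the defaults need one adjustment: with only a few dozen
training volumes, an effective batch of 16 yields 2–4 optimizer updates per
epoch, far too few for convergence inside the short smoke-test schedules.
The packaged smoke experiments therefore use lr 0.02 with accumulation 1–2.
This was fixed once when the experiments were designed.

## Progressive channel pruning

Every `interval_epochs` (default 5) epochs, the magnitudes |γ| of all
currently unmasked, unprotected batch-norm channels are pooled across
layers and the nearest-rank *lower* quantile at `ratio_per_step` (default
0.05) becomes the threshold τ; channels with |γ| **strictly below** τ are
masked (ties kept), their γ/β and the dependent pointwise rows, downstream
depthwise kernels and downstream pointwise/head columns are zeroed, and
each layer always retains at least one channel. Because the ratio applies
to *remaining* channels, s steps at ratio ρ leave a fraction `(1−ρ)ˢ`, up
to integer rounding. Pruning stops once the cumulative removed fraction
reaches `target_total_fraction`: an uncapped 100-epoch schedule would
remove ~64% of channels and overshoot the published compressed budget, so
the stopping point is an explicit knob. Its default 0.34 was calibrated
once by `calibrate_prune_target()` so the compacted full-size model lands
on the published 0.49 M parameters (≈47% parameter reduction); the
calibration draws channel scales from a half-normal distribution as a
synthetic stand-in for a trained, L1-regularized scale distribution, since
training the full-size model is beyond one CPU.

Protected from pruning: the stem (its output width is the contract of every
stage), the classifier head, and the entire fusion block — the gate because
its input dimension is structural, the branch batch-norms because the fused
output is a *sum* over branches, so per-branch channel removal would break
the summation. The quantile pool is global across layers (the
network-slimming convention); a per-layer mode exists behind a flag.

Masking and physical removal are distinct: during training channels are
only zeroed (so optimizer state stays aligned), and `compact()` later
rebuilds the model with masked channels deleted. Masked and compacted
models are forward-equivalent — in evaluation mode a masked channel's batch
norm emits exactly `(x − m)·0 + 0 = 0`, and everything it feeds is zeroed —
and this equivalence is the central correctness oracle of the pruning
tests, checked on 20 randomized architectures.

## Complexity profiling

`count_params()` enumerates trainable entries (kernels, weight matrices,
biases, batch-norm scale/shift; running statistics excluded).
`count_flops()` counts `2 × out_positions × C_in × K³ × C_out` per
convolution (a multiply–add is two operations; depthwise layers contribute
one output channel per group; dilation does not change the count) and
`2·m·n` per fully connected layer. Batch norm, activations, pooling, the
attention module's elementwise work and the small fusion-gate MLP are
excluded — a scoping choice users should know when reconciling with other
profilers. Model size is `para × b` bytes (`b = 4` for float32) and the
mebibyte figure divides by 2²⁰, the only convention consistent with all
published size rows. Performance density is accuracy (percent) per million
parameters, `acc / (para/10⁶)`; the printed formula's extra "×100" is
absorbed by expressing accuracy as a percentage, which is the only reading
that reproduces the published table cells.

## Evaluation statistics

Confusion-matrix metrics follow the standard definitions, with undefined
ratios (zero denominators) reported as `NA` rather than coerced to zero.
The positive class is the disease label 1. AUC is the Mann–Whitney pair
statistic computed from midranks (ties count one half) and is tested
against brute-force pair enumeration. Fold comparison uses the one-sample
t-statistic `(x̄ − μ₀)/(s/√n)` with the n−1 sample standard deviation and an
upper-tail Student-t p-value on n−1 degrees of freedom — the one-sided
reading is the one consistent with published (t, p) pairs at df 4; a
two-sided alternative is available. Cross-validation is stratified at the
*subject* level so multi-scan subjects can never leak between training and
test folds; minority-class oversampling and augmentation touch training
folds only.

## The synthetic cohort

Real cohorts of preprocessed MRI are access-controlled, so the package
generates brain phantoms: an ellipsoidal "brain" (semi-axes 0.42 of each
dimension) at base intensity 0.7 with a smoothed Gaussian texture (sd 0.05,
smoothing σ 1.5 voxels), zero background, clipped to [0, 1]. The disease
class multiplies a fixed signal subregion — an in-plane disc of radius
`0.25·min(H,W)` restricted to the axial slab `signal_slab` — by
`1 − effect_size`, emulating localized atrophy-like intensity loss. The
default geometry is 73 axial slices (inferior→superior, 0-based, half-open
windows) of 96×96 voxels, the slab at [20, 40); smoke-scale cohorts use
32×48×48 with the slab at the same relative depth, [9, 18). Each sample is
generated from a substream indexed by `(seed, draw)`, so cohorts are pure
functions of their spec and generation order is irrelevant; with
`effect_size = 0` the two class-conditional distributions are identical by
construction.

What the phantoms do *not* emulate: anatomy, registration artifacts,
scanner effects, inter-subject variability beyond the texture field. A
model that separates phantoms has demonstrated that the pipeline —
generation, augmentation, training, pruning, evaluation, occlusion — is
mechanically sound and that the class signal at the stated effect size is
learnable; it says nothing about accuracy on real MRI.

## Interpretability

`occlusion_profile()` masks consecutive axial slice windows (default
non-overlapping windows of 10 slices, fill value 0 — the post-normalization
background) and recomputes accuracy; the window with the largest drop
localizes the decision-relevant depth range. On phantom cohorts the
maximum-drop window co-localizes with the signal slab for converged models,
a seeded statistical property in the acceptance suite (≥8 of 10 seeds).
`layer_importance()` reports each convolutional layer's mean absolute
weight, masked channels excluded.

## Problem sizes and numerical choices

The packaged experiments run at deliberately reduced sizes chosen for a
single CPU: smoke cohorts of 40 (cross-validation) or 18 (occlusion) subjects
per class at 32×48×48, a three-stage network with widths (8, 16, 32), 12–15
epochs. Batch-norm uses ε = 1e-5 and momentum 0.1 on running statistics
(biased batch variance, matching the common framework convention).
Numerical equivalence between masked and compacted models is asserted at
1e-5 relative tolerance; gradient checks at 1e-4 relative on the
largest-gradient entry per parameter tensor. He-style normal initialization
is used for all convolution and linear weights, unit/zero for batch-norm
scale/shift, seeded per layer-build so identical seeds give identical
models.

## Known limitations

- The engine is CPU-only and single-threaded; it is a study implementation
  of the method, not a production trainer. Full-size (0.92 M parameter)
  models instantiate and profile quickly, but training them is out of reach
  without accelerators.
- The exact stage count/widths of the reference architecture are not
  published; the calibrated ladder reproduces the parameter budget, not
  necessarily the authors' topology.
- FLOPs scope excludes the gate MLP and elementwise work (documented
  above), so totals can differ slightly from profilers that include them.
- The fold t-test treats folds as exchangeable draws; with five folds its
  power is limited and the type-I calibration in the tests is asymptotic in
  the number of replicates.
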