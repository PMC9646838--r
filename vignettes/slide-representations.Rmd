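---
title: "Fixed-size slide representations from top-K patch activation maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fixed-size slide representations from top-K patch activation maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

A whole-slide histopathology image (WSI) is a gigapixel image whose clinical
label — tumour status, subtype, survival — is attached to the slide, not to
any pixel. The standard decomposition tiles the slide into fixed-size
patches, scores each patch with a CNN, and then faces the aggregation
problem: slides have wildly different numbers of patches, and the
class-relevant tissue may occupy a small minority of them. Post-hoc pooling
(the mean or maximum of patch probabilities) throws away everything about
*how* a patch achieved its score; sequence or graph models give up the
convenient image structure.

This package implements a third route: convert every slide, whatever its
size, into one fixed-size, image-formatted matrix, and let an ordinary small
CNN operate on that.

## The representation

Three stages, for a slide with patches $x_1, \dots, x_n$ and a patch-level
scorer that outputs a class probability $P_C$ and exposes an internal
convolutional layer with $M$ activation maps $A^m \in \mathbb{R}^{H\times W}$:

1. **Top-K selection.** Patches are ranked by $P_C$; exact ties rank the
   patch with the higher mean activation first, and any remaining ties keep
   the original patch order. The top $K$ patches are kept ($K = 50$ by
   default; it is the single most important tuning parameter, and the
   `k-sweep` CLI command measures validation AUC over a list of candidates).

2. **Patch representation.** For each selected patch, every activation map
   receives an importance score
   $$\alpha_m = \mathrm{ReLU}\Big(\sum_i \sum_j \frac{\partial P_C}{\partial A^m_{ij}}\Big),$$
   i.e. the gradient of the class objective is summed over the map and
   clamped at zero, which *eliminates negatively-contributing maps before
   they are combined*. This differs deliberately from original
   gradient-weighted class activation mapping, which averages gradients into
   signed weights and rectifies only the combined map; the original variant
   is available via `slide_to_hipomap(variant = "original")` for
   comparison. The class feature map is the weighted sum
   $T_{ij} = \sum_m \alpha_m A^m_{ij}$ (no second rectification: the exposed
   activations are post-ReLU and the $\alpha$'s are already non-negative,
   so $T \ge 0$), and the patch's representation is the flattening of $T$
   sorted in descending order — a length-$H\cdot W$ profile of activation
   mass that is invariant to where in the patch the activation occurred.

3. **Aggregation.** The $K$ sorted vectors are stacked into
   $X \in \mathbb{R}^{K \times (H\cdot W)}$ and the rows are sorted by
   descending row sum, so the most activated patches sit at the top. Slides
   with fewer than $K$ patches are padded with all-zero bottom rows
   (`pad_count` records how many), preserving the fixed shape the
   downstream CNN requires.

The result is monotone along both axes by construction, which is what makes
it image-like: nearby entries carry similar activation mass, so small
convolutions are meaningful.

### Numerical conventions

* $\alpha_m$ uses the plain double sum of gradients, not the
  $1/(HW)$-averaged variant; `compute_importance(reduce = "mean")` restores
  the average. The two differ only by a positive constant and therefore
  produce identical maps up to scale.
* The gradient target defaults to the post-sigmoid/softmax probability
  $P_C$; `wrt = "logit"` switches to the pre-activation score. The
  probability target scales every gradient by $p(1-p)$, which vanishes on
  confident patches and is largest on uncertain ones — on a well-trained
  scorer this *inverts* the intensity ordering of the map (ambiguous
  patches outshine confident lesions) and measurably degrades the
  downstream CNN. The packaged experiments therefore use the logit target
  (on the package's synthetic cohorts: held-out AUC ~0.99 versus ~0.8 with
  the probability target, reproducible via the acceptance materials); the
  probability target remains the default for fidelity to the method's
  definition and behaves equivalently when the scorer is not saturated.
* Row-sum ties in the aggregation are resolved by a stable sort on the
  pre-sort row order; patch-score ties by mean activation, then patch
  index. Together these make the map invariant to the order in which a
  slide's patches are presented.
* No per-map normalisation is applied to $X$: absolute intensity is
  meaningful across slides (more severe slides produce brighter maps), and
  per-map min–max scaling would destroy exactly that signal. The
  slide-model trainer divides all training maps by one cohort-level scalar
  (the maximum absolute entry) purely to keep optimisation well-scaled; the
  scalar is stored in the model and reapplied at prediction time.

## The slide-level CNN

`slide_model_config()` describes the downstream network: three
convolution + pooling blocks (3×3 kernels, 2×2 max pooling by default —
an average-pooling switch exists), a fully connected ReLU layer, and a
task head: sigmoid (binary), softmax (subtype), or linear (Cox survival
and survival regression). The reference sizes are 64 kernels per block and
a 1024-unit dense layer; the package's own experiments use 16 kernels and
64 units, which train in seconds on one CPU core at the synthetic map size
(16 × 64) with no measurable loss of accuracy at cohort sizes of a few
hundred slides.

Losses: cross-entropy for classification, ordinary least squares for
regression, and for survival the Cox negative log partial likelihood with
the Breslow convention for ties,
$$-\frac{1}{d}\sum_{i: \delta_i = 1}\Big[r_i - \log \!\!\sum_{j: t_j \ge t_i}\!\! e^{r_j}\Big],$$
normalised by the event count $d$ so the loss scale is batch-size
invariant. Survival training always uses full-cohort batches so risk sets
are complete; mini-batched partial likelihoods are biased for small
batches and nothing here is large enough to need them. Training with all
subjects censored is refused (the likelihood is undefined). Evaluation uses
Harrell's concordance over admissible pairs (risk ties count ½), AUC by the
rank statistic, micro-/macro-F1 for subtypes, and RMSE / $R^2$ for
regression.

## The CNN engine

No deep-learning runtime ships with this package's dependency set, and the
representation needs something most runtimes hide anyway: the gradient of a
chosen class objective with respect to a *named internal layer's*
activations, plus the ability to re-run the forward pass from that layer
with perturbed activations (which is how the test suite finite-differences
every gradient the package computes). The engine is therefore explicit:
stride-1 same-padded convolution (im2col + BLAS), ReLU, non-overlapping
max/average pooling, global average pooling, dense layers, and SGD with
momentum, all seeded and deterministic. Parameter gradients, pooling
adjoints and the class-gradient path are verified against central finite
differences and explicit-loop oracles in the test suite; agreement is at
rounding level (relative error ~1e-10, asserted at 1e-3).

The default patch scorer is an average-pooling stem (halving resolution)
followed by three convolution blocks, global average pooling and a dense
head. The stem exists for CPU economy; on 64 px patches the exposed layer
is then 8×8, so a slide map at $K = 16$ is a 16×64 matrix. Any other model
can be used in its place provided it honours the scorer contract
(probabilities plus exposed activations and gradients).

## The synthetic cohort generator

Real WSI cohorts are large, private, and unnecessary for verifying the
machinery, so the generator builds slides with the statistical structure
the method assumes and nothing more:

* a slide is a variable-size bag of 64 px RGB patches (8–300 per slide,
  configurable);
* background patches are low-frequency Gaussian blobs over a bright,
  pale-pink base, with per-pixel noise and a per-slide brightness jitter
  (scan-to-scan variation);
* lesion patches are high-frequency oriented stripes over a darker, purple
  base. Each lesion patch draws a *severity* in $[0.1, 1]$ that scales its
  intensity shift, stripe amplitude and tint simultaneously, so weak
  lesions approach background appearance;
* a per-slide fraction of background patches (uniform in [0, 0.3]) is
  replaced by low-severity draws from the lesion texture model (severity
  at most 0.35) while keeping the background label — the analogue of
  inflammation or fibrosis, which genuinely overlaps weak lesions and
  therefore scores an intermediate probability. Because the rate is a
  slide-level quantity (inflammation is a slide-level condition), naive
  mean pooling faces a slide-level nuisance, which is precisely the regime
  in which a representation of the top-K patches can outperform a scalar
  pooled score. Severity grading and artifacts together also keep the
  scorer away from saturation on a cohort's patch population;
* positive slides carry `round(f * n_patches)` lesion patches (floor of
  one, so requested signal always exists); negative slides carry none. A
  scalar `lesion_fraction` gives every positive slide the same fraction; a
  range draws a per-slide fraction uniformly, producing the burden gradient
  survival studies need;
* survival times are exponential with rate
  $\exp(\beta \cdot \text{burden})/s$, where burden is the slide's lesion
  fraction, $\beta$ = `hazard_coef` (default 2) and $s$ = `baseline_scale`
  (24 months) — proportional hazards by construction, matching the Cox loss
  being tested. Censoring is covariate-independent: one global exponential
  censoring rate is solved numerically so the expected censored fraction
  equals `censoring_rate`;
* for subtype cohorts (`n_classes` > 2), subtypes differ in stripe
  orientation;
* one integer seed drives a single RNG stream, so identical specifications
  reproduce byte-identical cohorts.

What the generator does **not** emulate: stain chemistry and H&E colour
statistics, pyramidal resolution levels, spatial correlation between
neighbouring patches, tissue-boundary geometry, or label noise. Passing
tests therefore demonstrate that the pipeline recovers the signal it is
pointed at under controlled conditions — not that it reaches any particular
performance on clinical material.

### A note on attainable concordance

With exponential event times, the concordance of even the *true* risk is
bounded well below 1: a pair with log-hazard difference $\Delta$ is
correctly ordered with probability $e^{\Delta}/(1+e^{\Delta})$. At
`hazard_coef` = 2 and burden confined to $[0,1]$, the oracle that reads the
true lesion burden achieves a concordance of roughly 0.61 on a uniform
burden gradient (about 0.69 at the degenerate extreme of a two-point burden
distribution) — the acceptance script computes this oracle value alongside
the model's own held-out concordance, and the model's proximity to the
oracle, not the absolute number, is the meaningful quantity. The trained
pipeline lands within a few points of the oracle while correlating strongly
with the latent burden (held-out Spearman above 0.5 is asserted in the
tests).

## Problem sizes used in the packaged experiments

* classification: 200 slides (12–48 patches each), lesion fraction 0.1,
  2,000 training patches, 10 epochs for the scorer, $K = 16$, 30 epochs
  for the slide CNN, 75/25 split;
* survival: 300 all-tumour slides, per-slide burden uniform in
  [0.05, 0.95], censoring 0.3; the Cox head is deliberately small (8
  kernels, 16 dense units) with average pooling and weight decay 0.01 over
  100 full-batch epochs — the partial-likelihood signal is weak at this
  cohort size (see the concordance note above) and a larger max-pooled
  network simply overfits likelihood noise;
* top-K fidelity: 40 slides of 80–120 patches, lesion fraction 0.15,
  precision measured at $K = 8$ so that positive slides carry at least as
  many lesion patches as the selection examines.

These sizes were chosen so that each experiment completes in about a minute
on a single CPU core while leaving the measured quantities comfortably away
from their decision thresholds.

## Preprocessing of real images

For users with plain RGB slide images, `detect_tissue()` blurs the
grayscale image (Gaussian, default sigma 2 px, applied by separable
band-matrix filtering with replicate-normalised edges truncated at
3 sigma) and thresholds it — Otsu by default, with a fixed fallback of 0.8
for degenerate (near-constant) images; tissue is the darker side, since
stain absorbs light and glass is bright. `extract_patches()` tiles from the
top-left origin with half-open non-overlapping tiles, discards trailing
partials, and keeps tiles whose tissue fraction reaches `min_tissue_frac`
(default 0.2). `color_normalize()` is the naive Reinhard-style per-channel
mean/sd transfer to a reference image, in RGB by default (LAB optional),
clipped to [0, 1]; normalisation is applied patch-wise after extraction.
Zero-variance channels are passed through shifted to the reference mean.
Pyramidal WSI containers are out of scope — any adapter that yields plain
RGB regions can feed this module.

## Known limitations

* The engine is CPU-only and intentionally small; it is not a general
  training framework, and large backbones (the multi-receptive-field and
  Inception-style networks used as scorers in the literature) are out of
  scope — the scorer contract is the extension point.
* The representation discards within-patch spatial layout (by design: the
  descending sort buys shape invariance) and between-patch spatial
  adjacency; spatially-aware aggregation is a non-goal.
* Mini-batch Cox training is not implemented; cohorts must fit in memory
  as full batches.
* Multiclass ranking uses one chosen class's probability for selection;
  which class should rank patches in a subtype study is application
  dependent.
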