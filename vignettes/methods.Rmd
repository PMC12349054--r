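---
title: "Dual-domain vessel segmentation: model, numerics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-domain vessel segmentation: model, numerics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wdvessel)
```

## The problem and the model

Retinal vessel segmentation assigns every pixel of a fundus image a
probability of belonging to the vasculature. Two properties make it hard:
vessel calibre varies by almost an order of magnitude within one image
(capillaries of 1–2 px next to trunks of 4–8 px), and the vessel-to-background
contrast is low and spatially inhomogeneous.

`wdvessel` implements a U-shaped dual-encoder network that attacks both
problems at once:

* a **wavelet convolution encoder (WCE)** works in the frequency domain. Each
  stage applies a 3×3 convolution (with batch normalization and ReLU), splits
  the result into the four single-level Haar subbands, processes only the
  approximation band (LL) with a second convolution, and reconstructs full
  resolution by the inverse transform, leaving the three detail bands
  untouched. The processed LL band — at half resolution — is what the next,
  deeper stage consumes; the full-resolution reconstruction feeds the skip
  and fusion paths.
* a **deformable convolution encoder (DCE)** works in the spatial domain.
  Each block runs a standard conv/BN/ReLU branch in parallel with a
  deformable branch in which a small convolutional head predicts, per output
  location and kernel tap, a 2-D sampling displacement; the input is then
  read at those fractional positions by bilinear interpolation. Branches are
  summed residually and a 1×1 convolution adjusts the channels. Max pooling
  after the first two of three stages halves the resolution while channels
  double (C′, 2C′, 4C′).
* a **gated fusion bottleneck** tokenizes the deepest fused features into
  P×P patches with learned per-patch positional parameters and runs two
  cross-attention branches in which each branch's keys are modulated by a
  logistic gate driven by the other branch,
  K̃ₐ = Kₐ ⊙ σ(K_b) + Kₐ, followed by
  softmax(Q K̃ᵀ/√D) applied to the *other* branch's values. The two outputs
  are concatenated token-wise, passed through a two-layer MLP, reshaped to
  the patch grid, bilinearly upsampled, projected by 1×1 convolution and
  added to the fused carrier.
* a **depthwise-separable decoder** restores resolution in three upsampling
  stages (bilinear ×2, 1×1 channel adjustment, depthwise separable
  convolution, additive skip) plus a final refinement stage that applies one
  more separable convolution and a 1×1 projection to a single logit map.
  Probabilities are the sigmoid of those logits.

All four components can be switched off individually; a disabled component
is replaced by a standard-convolution twin with the same interface, so every
ablation variant builds and trains. This is also the basis of a strong test
anchor: with its offset head zeroed (the initialization), the deformable
encoder must agree with its twin to floating-point accuracy.

## Geometry of the assembly

The published stage dimensions are not all mutually consistent (stage
outputs at H/4 beside a third-stage dimension of H/8, and four decoder
stages against three encoder resolutions). The package resolves this as
follows, which we believe is the only reading in which every printed shape
claim holds:

* both encoders emit stage outputs at H, H/2 and H/4 with channels C′, 2C′
  and 4C′; the WCE additionally carries its processed LL band (at H/8 after
  stage 3) from stage to stage;
* fusion is a shared 1×1 convolution over the concatenated stage outputs,
  giving skips `fout1` (2C′ @ H), `fout2` (4C′ @ H/2) and `fout3`
  (8C′ @ H/4);
* the bottleneck operates at H/8: the fused stage-3 map (in both
  concatenation orders, sharing the projection weights) is max-pooled once
  more, attended, and returned as `fout4` (8C′ @ H/8);
* the decoder performs exactly three spatial upsamplings
  (H/8 → H/4 → H/2 → H) and a final full-resolution refinement stage that
  deliberately has no skip from the raw input image.

## Training

The loss is the equally weighted sum of binary cross-entropy and one minus
the soft Dice coefficient (smoothing constant 1 in numerator and
denominator, so a perfect prediction attains loss 0 exactly). The BCE term
is evaluated **from the logits** in the numerically stable softplus form;
its pullback `σ(z) − m` does not vanish when the sigmoid saturates, which
matters because an early unlucky step can otherwise silence the gradient
permanently. Optimization uses Adam (β₁ = 0.9, β₂ = 0.999) at an initial
learning rate of 10⁻³, decayed tenfold every 50 epochs, batch size 4, with
global gradient-norm clipping at 1 — the clipping guards the first epochs,
where the zero-initialized output head unfreezes.

Three initialization choices are deliberate: convolutions are He-normal;
the offset head of every deformable block starts at **zero**, so training
begins in the standard-convolution regime (which is also the test anchor);
and the output 1×1 head starts at zero, so the network begins at probability
0.5 everywhere instead of a saturated sigmoid.

Normalization statistics are computed per image over the spatial dimensions
during training (batch normalization at effective batch size one) and
tracked as running averages used at inference. This keeps every forward
pass deterministic and batch-size independent, which the package's
reproducibility guarantees (equal seeds ⇒ bit-identical runs) rely on.

Differentiation is reverse-mode on a tape built by the package itself, with
compiled kernels for the convolution, deformable sampling, pooling and
resizing operations; the test suite verifies every analytic gradient
against central finite differences through the entire network. One genuine
non-smoothness exists: the bilinear read is only one-sided differentiable
exactly on the integer grid, i.e. precisely at the zero-offset
initialization. The one-sided derivative is used there, as in all common
deformable-convolution implementations; the gradient checks therefore
perturb the offsets off the grid first.

## Numerical conventions

* **Haar transform.** Subbands use the ¼-weighted sums over 2×2 blocks, so
  LL + LH + HL + HH reproduces the top-left block pixel exactly and the
  inverse is exact to machine precision (the suite requires < 10⁻⁶ over 100
  random maps). Established wavelet libraries normalize by ½ per level; the
  factor 2 between conventions, and the correspondence of our
  column/row-difference bands to their vertical/horizontal detail bands, is
  verified, not assumed. Odd spatial dimensions are rejected rather than
  padded — silent padding would break the exact-reconstruction surface; the
  preprocessing contract (inputs divisible by 8) makes padding unnecessary.
* **Bilinear sampling** uses an implicit zero border, consistent with the
  zero padding of the parallel convolution branch. Bilinear resizing aligns
  the corner pixels.
* **Metrics.** Scores with empty denominators are reported as `NA` with an
  explicit flag, never as 0. AUC is the midrank Mann–Whitney statistic,
  which equals the trapezoidal ROC area with half credit for ties; the
  binarization threshold for the counting metrics defaults to 0.5.

## The phantom generator

Real fundus datasets cannot be bundled, so the package generates
**vascular phantoms**: recursive bifurcating centerlines (a random walk
whose curvature is bounded by the `tortuosity` parameter, with daughters
carrying 0.55–0.75 of the parent calibre) stroked into a tube mask, rendered
dark on a bright background with a smooth low-frequency illumination field
(three broad Gaussian bumps scaled to `illumAmplitude`) and additive
Gaussian noise. Defaults (128 px, two trees, four bifurcation levels, widths
1–8 px, contrast 0.45, illumination ±20 gray levels, noise SD 8) were chosen
so the vessel fraction lands near the ~10% typical of fundus photographs
while covering the full calibre range; `smallPhantomConfig()` scales the
geometry proportionally to 64 px (two trees, three levels, widths 1–5) for
fast end-to-end runs. Generation is deterministic per seed down to the byte.

The phantoms reproduce the statistical challenges the architecture targets —
multi-scale curvilinear structure, low contrast, illumination heterogeneity,
noise — but not fundus photometry: there is no optic disc, fovea, pathology,
or color. Passing the end-to-end tests therefore demonstrates that the
implementation can represent and learn this class of structures, not that it
attains any particular accuracy on clinical data.

## Problem sizes used by the tests

The suite exercises components at small sizes where brute-force oracles are
exact and cheap (5×5 to 8×8 maps for the loop oracles, 32×32 for whole-model
gradient checks) and runs one full end-to-end training: the complete network
(C′ = 16) on eight 64-px phantoms for at most 200 Adam steps, which reaches
a training Dice above 0.95, plus short completion runs of the four ablation
variants. Because the learning-rate decay is defined on a full-scale horizon
(50 epochs over an augmented training set, i.e. thousands of updates), the
200-step desk run lies entirely inside the first constant-rate phase and is
trained at 10⁻³ throughout. These sizes are the package's reference desk-scale experiment;
all of them are regenerated from seeds at run time.

## Known limitations

* Single-level Haar decomposition only; other mother wavelets would slot in
  behind the same subband interface but are not implemented.
* Single-head attention without dropout; no modulation masks in the
  deformable branch (offsets only).
* Whole-image training on size-locked inputs: a model is built for one
  input size (the positional parameters live on a fixed patch grid), and
  prediction pads reflectively only up to that size.
* CPU-only, image-at-a-time execution; practical for the desk-scale
  experiments the package targets, not for training on full clinical
  datasets.
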