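# wdvessel

Retinal vessel segmentation in fundus-style images with a **dual-domain
encoder–decoder network**, implemented and trainable entirely in R.

Segmenting the retinal vasculature is hard for two reasons: vessel calibre
spans almost an order of magnitude within a single image, and the
vessel-to-background contrast is low and spatially inhomogeneous. The model
combines four components that address these jointly:

* **Wavelet convolution encoder (WCE).** Each stage convolves, splits the
  feature map into the four single-level Haar subbands
  (LL = ¼(F₀₀+F₀₁+F₁₀+F₁₁) and the three ¼-weighted difference bands),
  convolves only the approximation band, and reconstructs by the exact
  inverse transform — frequency-domain context with perfect reconstruction.
* **Deformable convolution encoder (DCE).** Convolution whose kernel taps
  sample at learned fractional displacements,
  y(p) = Σₙ w(pₙ)·x(p + pₙ + Δpₙ), evaluated by bilinear interpolation —
  receptive fields that bend along vessels.
* **Gated fusion bottleneck.** Patch tokens from both encoders exchange
  information through gated cross-attention,
  Z_a = softmax(Q_a(K_a⊙σ(K_b)+K_a)ᵀ/√D)·V_b.
* **Depthwise separable decoder.** Dense K×K convolutions factorized into
  per-channel spatial filtering plus 1×1 channel mixing, cutting parameters
  by the factor 1/K² + 1/C_out (over 88% in deep layers).

The package also provides the full training stack (tape-based reverse-mode
differentiation with compiled kernels, Adam with step decay, composite
BCE + Dice loss), the standard fundus preprocessing pipeline (grayscale,
z-score normalization, CLAHE, eightfold dihedral augmentation), pixel-wise
metrics (accuracy, sensitivity, specificity, F1/Dice, AUC), and a seeded
**synthetic vascular-phantom generator**, so every component — including
end-to-end training — runs with no external data.

## Worked example

Generate eight 64-px phantoms, train the full network for 200 Adam steps and
evaluate on the training set:

```r
library(wdvessel)

recs <- lapply(1:8, function(i) {
  ph <- generatePhantom(smallPhantomConfig(seed = i))
  preprocessRecord(list(image = phantomImage(ph),
                        mask  = phantomMask(ph), id = i))
})

net <- vesselNet(inputSize = 64, baseChannels = 16, seed = 1)
net
#> VesselNet dual-domain segmentation network
#>   input: 64 x 64 grayscale, base channels C' = 16, patch size 2
#>   wavelet encoder: on | deformable encoder: on
#>   gated fusion bottleneck: on | separable decoder: on
#>   skip mode: add | batch norm: on
#>   trainable parameters: 2,390,425

fit <- trainModel(net, recs, epochs = 100, batchSize = 4,
                  maxSteps = 200, decayEvery = 1000, seed = 1)
res <- evaluateModel(fit$model, recs)
round(unlist(res$summary$mean), 3)
#>   Acc    Se    Sp    F1  Dice   AUC
#> 0.997 0.992 0.997 0.986 0.986 1.000
```

The per-pixel probabilities come from `predictProb(fit$model, image)`; a
Dice/F1 near 0.99 on the training phantoms confirms the network can
represent and learn multi-scale curvilinear structure (it says nothing
about clinical data — see the methods vignette).

The closed-form parameter accounting of the separable decoder:

```r
paramAccounting(3, 64, 256)$percent_reduction
#> [1] 88.49826
```

A command-line interface wrapping the same functions (verbs `synth`,
`train`, `eval`, `predict`, `ablate`) is installed at
`inst/cli/wdvessel.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/wdvessel.R", package="wdvessel"))')" \
    synth --out phantoms --n 8 --size 64 --seed 1
```

## Package layout

* `R/` — autodiff tape, layer kernels' wrappers, the four architecture
  components, model assembly, training, preprocessing, metrics, phantom
  generator, pipeline commands.
* `src/ops.cpp` — compiled forward/backward kernels (conv, depthwise,
  deformable with bilinear offset sampling, pooling, resizing).
* `vignettes/methods.Rmd` — model description, numerical conventions and
  design rationale.
* `tests/testthat/` — unit, property and acceptance suites with independent
  brute-force oracles.
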