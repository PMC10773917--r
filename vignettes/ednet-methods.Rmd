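---
title: "ED-Net methods: architecture, complexity accounting and desk-scale training"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ED-Net methods: architecture, complexity accounting and desk-scale training}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ednet)
```

## The model

ED-Net is a compact convolutional classifier for seven categories of eye
disease (bulging eyes, cataracts, crossed eyes, diabetic retinopathy,
glaucoma, uveitis, normal). It composes three block types:

* **ED_Conv** — a 7×7 stride-2 convolution from RGB to 64 channels
  (padding 3), the only layer that changes the spatial size;
* **ED_Resnet** — a residual bottleneck: 1×1 convolution halving the
  width, a depthwise convolution at the halved width, and a 1×1
  convolution restoring it, with an additive skip from block input to
  block output;
* **ED_Xception** — sequential 3×3, 5×5 and 7×7 same-width convolutions
  (paddings 1/2/3) followed by a 1×1 convolution that doubles the width.

The full network is one ED_Conv, then ED_Resnet(64),
ED_Xception(64→128), ED_Xception(128→256), ED_Resnet(256),
ED_Xception(256→512), and a global-average-pool + linear head to 7
logits. Every convolution is followed by batch normalization; the final
convolution of each block additionally applies the swish6 activation.
Class probabilities are the softmax of the logits,
$p_i = e^{z_i}/\sum_j e^{z_j}$.

The activation is a clipped swish: $\mathrm{swish}(x) = x\,\sigma(\beta x)$
with gate slope $\beta$ (default 1, optionally trainable), clamped so the
output is the constant 6 once the input reaches 6 — the same idea that
turns ReLU into ReLU6, bounding activations for stability.

```{r swish6}
curve(swish6(x), -6, 10, n = 801, ylab = "swish6(x)")
abline(h = 6, lty = 3)
```

## Structural choices the source table leaves open

The published structure table under-determines four things; each is an
explicit flag of `ednet_config()`:

* **"LBN"** is read as per-convolution batch normalization (the
  ubiquitous Conv/BN idiom). Convolution biases are dropped wherever a
  normalization follows, since the shift absorbs them.
* **Residual skip**: the prose says the input is "concatenated" onto the
  output, but the table's channel arithmetic (64 in, 64 out) balances only
  under elementwise addition. Addition is the default; true concatenation
  with a reconciling 1×1 projection is available (`resnet_skip =
  "concat"`).
* **Residual depthwise kernel**: the block diagram shows 5×5 where the
  table says 3×3; the table wins by default (`resnet_kernel = 3`).
* **ED_Xception convolution style**: the table writes plain convolutions,
  but the Xception heritage implies depthwise-separable ones, and the two
  readings differ by an order of magnitude in cost. Both are implemented
  (`separable_xception`), and `sweep_architecture_variants()` enumerates
  all 16 flag combinations, ranking them by mean relative error against
  the published totals of 2.68 M parameters and 0.16 G MACs. The
  best-ranked combination — depthwise-separable, no projection skips, 3×3
  residual kernel, additive skips — is the frozen package default.

```{r sweep}
head(sweep_architecture_variants(), 4)
```

A caveat the sweep makes quantitative: *no* combination reproduces the
published totals. The dense reading gives ≈7.4 M parameters and ≈93 G
MACs; the separable reading ≈0.56 M and ≈6.9 G. The published 0.16 G in
particular would require spatial downsampling beyond the stride-2 stem,
and the structure table's stride column contains none. The counter itself
is therefore validated independently on the standard VGG16 configuration,
whose published cells (138.36 M, 15.5 G) it reproduces exactly, and by a
weight-enumeration oracle on instantiated networks; the network's own
totals are reported as measured under the frozen reading.

## Complexity conventions

`count_params()` and `count_macs()` follow the conventions of standard
counters, which the published baseline cells match: a dense convolution
costs $k^2 C_{in} C_{out}$ weights and that many multiply-accumulates per
output position; a depthwise convolution $k^2 C$; a linear layer
$C_{in} C_{out} (+ C_{out}$ bias$)$; batch normalization carries
$2C$ parameters and no MACs; activations and pooling are free; one MAC is
counted as one "FLOP". Totals are exact integers before the
millions/billions scaling.

## Numerical choices

* **swish6 clamp branch.** The defining piecewise form omits $x = 6$;
  it is assigned to the clamp (value 6), making the function total. The
  literal piecewise form has a jump of $6 - 6\sigma(6\beta)$ at the
  threshold; a continuous `min(swish(x), 6)` variant is available via
  `continuous = TRUE`. The backward pass uses zero gradient on the
  clamped branch.
* **softmax** subtracts the row maximum before exponentiating;
  cross-entropy uses log-sum-exp. Ties in predicted class resolve to the
  first (lowest-index) class.
* **Pooling** rejects odd spatial dimensions rather than inventing a
  padding dialect: only the stride-2 non-overlapping case is defined.
* **Batch normalization** uses $\epsilon = 10^{-5}$ and running-statistic
  momentum 0.1, with the unbiased variance in the running estimate;
  inference uses running statistics.
* **Initialization** is Kaiming-style: zero-mean normal with variance
  $2/\mathrm{fan_{in}}$, drawn in a fixed layer order from
  `weight_init_seed`, so equal seeds give bitwise-identical networks.
* **Internal layout** is channels-last `(H, W, N, C)`: batch-norm
  statistics, global pooling and the channel contraction of a convolution
  all become contiguous column-major reshapes; a $k\times k$ convolution
  is $k^2$ shifted BLAS products, and the depthwise case (which BLAS
  cannot help with) is a small compiled kernel.

## Training recipe

`train_config()` defaults encode the recipe: SGD with classical momentum
0.9 and coupled L2 weight decay 4×10⁻⁴, batch size 64, 100 epochs,
initial learning rate 0.01 multiplied by 0.95 after each epoch. The decay
is deliberately per-epoch: applied per batch, 0.95 over ~5,400 steps
would collapse the rate to effectively zero and nothing would train.
Since the published protocol defines no validation split, the best model
is checkpointed by test accuracy, mirroring the two-way split; `evaluate`
and `predict` on a fit use that checkpoint. Loss is mean cross-entropy.
All shuffling derives from `(seed, epoch)`, so a run is reproducible
bit-for-bit.

## The synthetic generator

The real dataset (two Kaggle collections plus hospital photographs,
4,600 images, 3,451 train / 1,149 test, heavily imbalanced — 24
bulging-eyes vs 823 diabetic-retinopathy training images) is not
redistributable. `generate_synthetic_dataset()` emulates its *structure*:
the default `synthetic_spec()` reproduces the published per-class
train/test counts exactly, and each class gets a procedural motif on a
shared eye template — enlarged sclera (bulging eyes), bright lens opacity
(cataracts), off-center pupil (crossed eyes), scattered red lesions
(diabetic retinopathy), enlarged pupil (glaucoma), inflamed iris ring
(uveitis), plain eye (normal). Motif contrast scales with `separability`
$s \in [0,1]$ (at $s=0$ all classes render identically), and i.i.d.
Gaussian pixel noise with standard deviation `noise` is added and clipped
to $[0,1]$. Defaults $s = 0.9$, noise $= 0.02$ keep the task non-trivial
but learnable. Every image is rendered from its own derived seed, so
outputs are byte-identical across runs.

What the generator does *not* emulate: photographic texture, anatomical
variation, illumination, camera artifacts, label noise — any clinical
realism at all. A network that learns the synthetic task demonstrates
that the architecture, gradients and training loop work, not that it
diagnoses eye disease; the published 91.66% real-data accuracy is not
reproducible from this package and is not claimed.

## Desk-scale problem sizes

The package's own checks run at deliberately small scale, chosen once:

* correctness of gradients on a width-2/64 network at 8×8 input against
  central finite differences;
* the learning check trains a width-0.25 network on 32×32 synthetic
  images (48 train / 12 test per class, $s = 1$, noise 0, batch size 8,
  5 epochs, pinned seeds) and requires the checkpointed held-out accuracy
  to exceed 0.9 with a window-3-smoothed non-increasing loss trend;
* the full-width network is exercised at the native 224×224 input for
  shape and probability contracts.

Batch size 8 (rather than the full recipe's 64) at this scale simply
gives the optimizer enough steps per epoch to move; the learning-rate,
momentum and decay values are the recipe's own.

## Known limitations

* The published parameter/MAC totals for the network are not reproducible
  from the published structure table under any of the 16 structural
  readings swept; see above. The VGG16 fixture anchors the counter
  instead.
* The spatial trajectory (only the stem downsamples) is inferred from the
  stride column; at 224×224 this makes the literal network expensive to
  run, which is one more reason to doubt that reading, but it is what the
  table states.
* Training is CPU-bound base R + a small compiled kernel; it is meant for
  desk-scale study, not for reproducing GPU-scale results.
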