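---
title: "Lightweight anchor-free egg-candling detection: models, accounting and training"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lightweight anchor-free egg-candling detection: models, accounting and training}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eggcandler)
```

## The problem

After about five days of incubation, a candled fertile egg shows a dark
embryo spot and branching blood vessels, while an infertile egg transmits a
uniform glow. Removing infertile eggs early saves incubator energy and
prevents contamination. On an industrial tray (up to 7 x 9 = 63 eggs) this
is a multi-object detection problem with two classes, `fertile` and
`infertile`, and it must run on small embedded devices — hence the focus on
a *lightweight* detector.

`eggcandler` implements the full architecture family: the tiny anchor-free
baseline detector, its depth-wise separable variant, two slimmed backbones,
and the final lightweight model ("LDA" = slim backbone + depth-wise
separable convolutions + efficient channel attention). Every network is
described twice from a single symbolic graph: once for exact
parameter/FLOP auditing, once as an executable CPU network.

## Depth-wise separable cost model

A standard convolution with `m` input channels, kernel `k`, `p` output
positions per axis and `N` kernels costs `Sc = m k^2 p^2 N`
multiply-accumulates; the depth-wise separable factorization (a per-channel
`k x k` convolution followed by a `1 x 1` channel mixer) costs
`Sd = m k^2 p^2 + m p^2 N`. The ratio

```
Sd / Sc = 1/N + 1/k^2
```

is independent of `m` and `p`; with `k = 3` it approaches 1/9 for wide
layers, which is why substituting every 3 x 3 convolution shrinks the
detector from 5.033 M to 1.991 M parameters. `paper_conv_cost()` evaluates
these closed forms; the property suite checks the identity over random
tuples.

## Counting conventions (and how they were fixed)

The audit must reproduce the published size tables *exactly*, which pins
down several conventions that prose leaves open:

* **Convolutions carry no bias**; every convolution is followed by a
  batchnorm contributing 2 affine parameters per channel. The only biased
  convolutions are the three head prediction layers.
* **CSP transitions are 1 x 1.** Some drawings of the cross-stage-partial
  block show 3 x 3 entry/exit convolutions, but only 1 x 1 transitions (the
  standard CSP layout) reproduce the printed 88,512 / 65,280 / 42,048
  parameter counts, so the numbers win.
* **The Focus stem convolution is never substituted** in depth-wise
  separable builds, matching the upstream tiny-detector implementation.
  This is required to reproduce the depth-wise backbone totals (1.024 M,
  0.967 M) and the full-model totals (1.991 M, 1.935 M).
* **FLOPs** are 2 ops per multiply-accumulate, plus 4 ops per element for
  each batchnorm and each activation (`elementwise_ops = 4`, configurable);
  pooling, upsampling, concatenation and residual adds are free. This
  convention reproduces the published block FLOPs to the printed digit
  (e.g. 1145.24 M, 461.414 M at 80 x 80 x 96) and the backbone column
  exactly; the full-model cells agree within 0.05 %.

Every builder is validated against an *enumeration oracle*: the symbolic
count must equal the number of scalars actually allocated by
`init_params()` for the executable network.

One published backbone cell (slim mid-size variant, depth-wise build,
0.992 M) appears to be truncated rather than rounded: the
convention-consistent count is 992,520 = 0.99252 M, and the same convention
reproduces the corresponding *full-model* size 1.960 M exactly. The package
reports the exact integer and documents the 0.001 M discrepancy instead of
adjusting the convention to one cell.

## Architecture

The backbone is a cross-stage-partial pyramid with stage widths
24-48-96-192-384 and a space-to-depth Focus stem. The baseline uses CSP
depths (1, 3, 3, 1); the slim variants remove the first CSP block entirely
(the stride-2 convolution alone carries the channel expansion) and reduce
the mid-stage depths to (2, 2, 1) or (1, 1, 1). Spatial pyramid pooling
(stride-1 max-pools of 5/9/13, a standard choice validated by the 2.372 M
backbone total) precedes the last CSP block. The three outputs (strides 8,
16, 32; channels 96, 192, 384) feed a path-aggregation FPN and a decoupled
anchor-free head of hidden width 96: per level, a 1 x 1 stem, two 3 x 3
units per branch, and 1 x 1 prediction convolutions for class (2), box
(4) and objectness (1).

Efficient channel attention (ECA) can be inserted after each backbone
output: global average pooling, a channel-wise 1-D convolution whose odd
kernel adapts to the width (`k = 3` at 96 channels, `5` at 192 and 384),
and a sigmoid gate. The adaptive rule (gamma = 2, b = 1) is used rather
than a fixed `k = 3` at all widths; the two are indistinguishable in the
printed tables (13 vs 9 parameters on a ~1.93 M model), and the adaptive
rule is the one the attention method itself defines.

Decoding is the standard anchor-free rule: at cell `(gx, gy)` of stride
`s`, center `= ((gx + dx) s, (gy + dy) s)`, size `= (exp(dw) s, exp(dh) s)`,
score `= sigmoid(obj) * sigmoid(cls)`, followed by class-wise greedy NMS
(IoU 0.45, score floor 0.01 — unstated upstream defaults, exposed in the
API).

## The executable engine

No tensor/autodiff library is assumed: convolutions run as im2col + GEMM
(with a pure-GEMM fast path for 1 x 1 convolutions) in C++, depth-wise
convolutions and max-pooling as direct C++ loops, and everything else as
vectorized R. The backward pass is hand-derived per node kind and verified
against central finite differences to ~1e-7 relative error in the test
suite.

Batch normalization uses per-sample statistics over H x W in both training
and inference (instance-style normalization). At the reference batch size
of 2 the distinction from cross-batch statistics is minor, and per-sample
statistics make single-image inference deterministic without maintaining
running buffers.

## Training

The optimizer follows the reference recipe: SGD, initial learning rate
0.001, momentum 0.9, weight decay 0.0005 (applied to convolution weights
only), batch size 2, 600 epochs. The learning rate follows cosine
annealing with warm restarts,

```
eta_t = eta_min + (eta_max - eta_min) (1 + cos(pi T_cur / T_i)) / 2,
```

with annealing switched off for the final 70 epochs. Unstated details were
fixed as follows: restart period `T_i = 50` epochs (configurable);
`eta_min = eta_max / 100`; the switched-off tail holds `eta_min` (the
switch-off exists to settle near the optimum, so the floor is the natural
constant; holding the last annealed value is available as an option). For
runs much shorter than 600 epochs the default schedule uses a single
cosine cycle and scales the tail proportionally (70/600 of the run).

Label assignment is a deterministic center-radius rule: a cell is positive
when its center lies inside a ground-truth box and within 2.5 strides of
the box center, and is assigned to the nearest box. (The upstream dynamic-k
assignment is intentionally replaced: at desk scale the fixed rule is
deterministic and much simpler, at some cost in borderline-cell quality.)
The loss is `5 * (1 - IoU)` on positives plus binary cross-entropy on
objectness (all cells) and class (positives), normalized by the positive
count; its analytic gradients are finite-difference checked. Objectness
and class prediction biases start at `logit(0.01)` so the untrained model
predicts background, the usual focal prior.

## Synthetic trays

No real candling dataset is distributed, so `generate_tray()` renders
seeded synthetic trays: a dark noisy background; per cell, a jittered,
slightly rotated bright ovoid with a warm (R > G > B) tint; fertile eggs
get a dark elliptical embryo spot plus 3-5 branching random-walk vessels,
infertile eggs a uniform (slightly brighter) glow. The default infertile
fraction is 840/2111, mirroring the reference stock, and the supported
grids are 3 x 5, 5 x 7 and 7 x 9. Augmentation multiplies a dataset by
exactly 4: the original, one right-angle rotation, one horizontal mirror
and one gamma-contrast change per image, with per-image seeded parameters
and exact box remapping. Boxes are 0-based half-open internally and
1-based inclusive in the VOC XML files, converted only at the I/O boundary.

What the generator does *not* emulate: shell-texture variation, partial
occlusion by tray hardware, specular highlights, blood rings and other
early-mortality patterns, camera noise statistics. Passing the synthetic
training check therefore demonstrates that the architecture, loss,
assignment, optimizer and evaluation pipeline are wired correctly and can
fit a candling-like distribution — not that the reported real-data
accuracies transfer.

## Problem sizes used by the test suite

The published experiments train 600 epochs on ~5,800 augmented 640-pixel
images; the package's training check instead uses 16 seeded 7 x 9 trays at
192 x 192, 12 epochs, batch 2, learning rate 0.05 with one cosine cycle,
evaluated on 10 held-out trays over 3 seeds — sizes chosen so the whole
check trains two models from scratch on a single CPU in minutes. At this
scale the higher learning rate is what makes 12-epoch convergence
possible; the full-scale default remains 0.001. The model-size and FLOP
audits are exact and instantaneous at the full 640-pixel configuration.

## Known limitations

* The engine is CPU-only and double-precision; it is built for
  correctness and desk-scale experiments, not production training speed.
* Per-sample normalization means very small feature maps (1-2 cells per
  side at deep stages of tiny inputs) normalize over few positions; inputs
  of 96 pixels or more behave well.
* The synthetic mAP saturates quickly on the easy generator distribution,
  so small architectural differences (e.g. the attention block) are within
  seed noise there, unlike on the harder real data the attention mechanism
  was introduced for.
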