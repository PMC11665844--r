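---
title: "Model and methods: dilated dual-attention segmentation of haemorrhage CT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods: dilated dual-attention segmentation of haemorrhage CT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Intracerebral haemorrhage (ICH) appears on non-contrast CT as hyperdense
tissue inside the skull. Automated pixelwise segmentation is hard for three
reasons that shape every design choice in this package: lesions can be tiny
(a few pixels across), their contrast against surrounding parenchyma is
often low, and lesion pixels are a small fraction of each slice, so naive
pixel losses are dominated by background. `hemoseg` implements an
encoder--decoder network specialised for this regime, a hybrid objective, an
evaluation suite, a cross-validation harness, and a synthetic head-phantom
generator that reproduces the statistical shape of the task so the whole
pipeline is testable without clinical data.

## Architecture

The network is a U-shaped encoder--decoder built by `hemo_net()` from a
`model_config()`:

* **Encoder.** A ResNet-34-style backbone: a 7x7 stride-2 stem
  (batch-norm, ReLU), then four residual stages with the reference block
  counts (3, 4, 6, 3) and widths (64, 64, 128, 256, 512), so stage *l* runs
  at 1/2^*l* of the input resolution. A bottleneck (depth-50) recipe is
  available via `encoder_depth = 50`. The stem pool is a 2x2 stride-2
  max-pool (the reference recipe's 3x3 stride-2 pool gives the same output
  sizes on even inputs; one pooling primitive keeps the kernel set small).
  ImageNet initialisation of the encoder is supported as a flag for users
  who can supply weights, but no weights ship with the package and the flag
  errors with instructions otherwise; all built-in training starts from
  He-normal random initialisation.
* **Dilated-convolution-pooling (DCP) side branches.** Every encoder level
  except the first can carry a DCP branch (`dcp_levels`, default 2--5). A
  branch consumes the previous level's output and runs parallel 3x3
  convolutions at dilation rates 1, 2 and 4 (each padded by its rate,
  batch-normalised and rectified), concatenates the branch outputs,
  compresses them with a 1x1 convolution, and max-pools 2x2/stride 2. The
  pooled map is element-wise **added** to the stage output; the enriched sum
  is both the decoder skip and the next stage's input. Rates (1, 2, 4) give
  effective extents of 3, 5 and 9 pixels — geometric growth that still fits
  the smallest mid-level maps. The additive side-branch wiring keeps the
  plain backbone intact (`dcp_levels = integer()` is exactly the backbone)
  and uses the block's own pooling as the x2 aligner.
* **Self-attention bridge.** On the deepest enriched feature, a non-local
  block computes query/key/value tensors with 1x1 convolutions (query and
  key reduced by `attention_key_reduction = 8`, the non-local convention;
  value at full width), forms a positions-by-positions weight matrix by a
  row softmax of the query--key inner products, mixes the value vectors,
  projects with a 1x1 convolution, and adds the input back. No temperature
  or 1/sqrt(d) scaling is applied. Placing the block once at the bridge lets
  global semantic context steer the whole decoder.
* **Decoder.** Five steps of: bilinear x2 upsampling, concatenation of the
  matching encoder skip (steps 1--4; the full-resolution step has no skip),
  a residual block, then channel attention followed by spatial attention.
  Channel attention is squeeze-excitation (global average pool, bottleneck
  of ratio 16, logistic gate); spatial attention stacks the channelwise mean
  and max maps and convolves them with a 7x7 kernel into a positionwise
  logistic gate. Decoder widths default to (256, 128, 64, 64, 32), encoder
  widths halved per step. A 1x1 convolution and logistic squash produce the
  probability map; inputs must have sides divisible by 32 so the five
  halvings invert exactly. Bilinear upsampling (half-pixel centres) rather
  than transposed convolution avoids checkerboard artefacts.

The default configuration has about 31.2 M learnable parameters
(`count_parameters()`; the encoder alone is 21.3 M). Removing the DCP
branches or the bridge strictly reduces the count, which the tests use as a
structural ablation check.

## Objective

Training minimises `alpha * L_BCE + beta * L_Dice` (`loss_config()`,
default `alpha = beta = 1`):

* `L_BCE = -(1/N) * sum(y*log p + (1-y)*log(1-p))`, with probabilities
  clamped to `[1e-7, 1 - 1e-7]` before logarithms (the formula itself has no
  guard against `log 0`).
* `L_Dice = 1 - (2*sum(y*p) + s) / (sum(y) + sum(p) + s)` with smoothing
  `s = 1` (common practice; also resolves the empty-mask 0/0 case to 0 loss).

Cross-entropy gives stable, well-scaled gradients; the Dice term directly
targets overlap and counteracts the class imbalance. The training-time loss
node carries a hand-derived gradient that the tests check against central
differences.

## Evaluation metrics

Per slice, from pixel confusion counts: Dice `2TP/(2TP+FP+FN)`, Jaccard
`TP/(TP+FP+FN)`, sensitivity `TP/(TP+FN)`, specificity `TN/(FP+TN)`, and
pixel accuracy `(TP+TN)/(TP+TN+FP+FN)`. Degenerate denominators follow the
usual benchmark conventions: empty truth with empty prediction scores 1
(sensitivity, Dice, Jaccard), empty truth with false positives scores 0, and
symmetrically for specificity. Aggregation reports the per-metric mean and
*population* standard deviation across slices. Reports are tibbles with
`tidy()`/`glance()` methods and an `autoplot()`.

## Training protocol

`train_fold()` runs mini-batch Adam at a constant learning rate (default
1e-4, batch 4, up to 150 epochs) and scores the test slices after every
epoch; a strictly better mean test Dice overwrites the saved checkpoint, so
the returned model carries the best—not last—weights. Everything (weight
initialisation, batch order, augmentation draws) derives from one seed, and
two runs with the same seed produce bit-identical logs. Selecting the
checkpoint on the *test* fold is optimistic as a protocol—there is no third
split—so the evaluator is injectable (`eval_fn`) and users with enough data
can hold out a validation set by passing it as `test_pairs` and scoring the
true test set afterwards. `cross_validate()` rotates a seeded, round-robin
fold manifest (`five_fold_split()`) so every slice is test-scored exactly
once; splitting is at slice level, matching practice on slice-annotated
collections (a patient-grouped split is advisable when patient identifiers
exist, and can be expressed by constructing the manifest directly).

Augmentation (training pairs only, never test pairs) applies random
rotation within +/-30 degrees, horizontal/vertical flips, scaling 0.9--1.1,
linear contrast gain 0.8--1.2 and additive Gaussian noise. Geometric
operations move image and mask together (bilinear for the image,
nearest-neighbour for the mask so it stays binary; zero fill outside the
original support); photometric operations touch the image only. The
magnitudes are conventions chosen to deform without destroying few-pixel
lesions.

## The phantom generator

`generate_slice()` draws, deterministically from a seed: a dark background,
a bright elliptical skull ring (intensity about 0.95, default thickness 3
px), mid-intensity parenchyma (about 0.45) with smooth low-frequency cosine
texture, and 1--3 lesions placed strictly inside the brain—deformed
ellipses (low-order harmonic radial perturbation, controllable so disc-area
bounds are assertable) with base radius 2--5 px at a contrast of 0.08--0.25
above parenchyma—plus Gaussian acquisition noise (sigma 0.02), clipped to
[0, 1]. The mask is the exact union of lesion supports. Under the defaults,
lesion prevalence stays in the low single-digit percent range, reproducing
the class-imbalance regime, and the contrast range keeps lesions near the
detectability floor.

The phantom emulates the *statistical shape* of haemorrhage CT—tiny,
low-contrast, irregular bright blobs inside a skull—not its radiometry:
there are no Hounsfield units, no beam hardening or streaks, no 3-d
anatomy, and no haemorrhage subtypes. Tests passing on phantoms therefore
validate the machinery (shapes, gradients, protocol, reproducibility, I/O)
and the learnability of the intended contrast cue; they do not certify
clinical performance.

## Numerical choices

* The network core is a small reverse-mode autograd tape in R with C++
  (RcppArmadillo) kernels for im2col GEMM convolution, 2x2 max-pooling and
  channelwise max. All arithmetic is double precision, single threaded, and
  seeded through R's RNG, which is what makes bit-exact reproducibility
  claims testable.
* Batch-norm uses batch statistics in training (momentum 0.1 on running
  buffers, eps 1e-5) and running statistics in evaluation. Closed-form layer
  tests put normalisation in an exact pass-through state (unit scale, zero
  shift, running variance `1 - eps`) to decouple the algebra from running
  statistics.
* Max-pool and channelwise-max ties break to the first scanned index; no
  behaviour depends on it.
* Binarisation uses `p >= threshold` (default 0.5), so exact-threshold
  pixels count as lesion.
* Convolutions after which batch-norm follows carry no bias; 1x1 heads and
  attention projections do.

## Scale of the built-in experiments

The test-suite and `scripts/acceptance.R` run entirely on phantoms at desk
scale — 32x32 and 64x64 slices, 4--64 slices per experiment, slim network
widths (8--64 channels) alongside the full-width default for structural
checks. These sizes were chosen so the whole suite runs on a single CPU in
minutes while still exercising every code path; the full-width,
512x512-slice configuration is the same code with larger numbers.

One empirical property deserves a plain statement. Training **from random
initialisation** with the adopted constant learning rate of 1e-4 moves
Adam's iterates by about 1e-4 per parameter per step, so memorising even 8
phantom slices takes on the order of 10^4 optimiser steps — hours on one
CPU. The protocol's rate is designed for *fine-tuning a pretrained
encoder*, which is not available offline. The suite therefore demonstrates
end-to-end trainability (Dice about 0.95 by memorisation) at learning rate
1e-2 on small phantoms, and separately runs the faithful 1e-4 protocol to
check the qualitative property that the loss decreases; the Dice target
under the faithful protocol is asserted and documented as failing at this
compute scale rather than silently relaxed.

## Known limitations

* Binary lesion-versus-background only; no subtype classification, no 3-d
  context across slices.
* No pretrained encoder weights are bundled; `use_pretrained_encoder`
  requires the user to supply weights (the flag otherwise errors).
* CPU-only and double precision: faithful and reproducible, but orders of
  magnitude slower than a GPU framework at clinical scale.
* Checkpoint selection on the test fold is optimistic; see above.
* The phantom's realism limits are listed in its section; conclusions about
  clinical data require clinical data.
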