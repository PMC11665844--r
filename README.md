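# hemoseg

Segmentation of intracerebral haemorrhage (ICH) on axial CT slices with a
dilated-convolution, dual-attention encoder–decoder network — implemented
natively in R, with no external deep-learning framework.

## The problem

Haemorrhage appears on non-contrast head CT as hyperdense tissue. Automated
pixelwise delineation is clinically valuable (volume estimates, triage) but
hard: lesions can span only a few pixels, their contrast against parenchyma
is low, and lesion pixels are a tiny fraction of each slice. `hemoseg` is
aimed at researchers working with slice-annotated CT collections (hundreds
of positive slices) who need a reproducible segmentation pipeline, and at
methodologists who want a fully inspectable reference implementation of
this architecture family.

## The model

A U-shaped network (`hemo_net()`):

* **Encoder** — ResNet-34-style stages (widths 64, 64, 128, 256, 512; stage
  *l* at 1/2^*l* resolution).
* **DCP branches** — at encoder levels 2–5, parallel 3×3 convolutions at
  dilation rates 1/2/4 (merged by concatenation, compressed 1×1, max-pooled)
  are added to the stage outputs, widening the receptive field for small
  lesions.
* **Self-attention bridge** — a non-local block on the deepest feature:
  softmax(q·k) position-pair weights mix value vectors, so global context
  guides decoding.
* **Decoder** — five steps of bilinear ×2 upsampling, skip concatenation,
  a residual block, and channel-then-spatial attention gating; a 1×1
  convolution plus logistic squash yields the probability map.

Training minimises the hybrid objective

```
L = α·L_BCE + β·L_Dice,   α = β = 1
L_BCE  = −(1/N) Σ [ yᵢ log pᵢ + (1−yᵢ) log(1−pᵢ) ]
L_Dice = 1 − (2 Σ yᵢpᵢ + s) / (Σ yᵢ + Σ pᵢ + s)
```

with Adam (lr 1e-4, batch 4, ≤150 epochs) under five-fold cross-validation;
after each epoch the test fold is scored and the best mean Dice checkpoint
is kept. Evaluation reports Dice, Jaccard, sensitivity, specificity and
pixel accuracy per slice and as mean ± sd.

A seeded phantom generator (`generate_slice()`) emulates the statistical
shape of the task — skull ring, textured parenchyma, 1–3 low-contrast
lesions of radius 2–5 px, acquisition noise — so the whole pipeline runs
and is tested without clinical data. See `vignettes/methods.Rmd` for the
full model account, parameter meanings and limitations.

## Worked example

```r
library(hemoseg)

# a small synthetic dataset: 6 phantom slices with ground-truth masks
pairs <- generate_dataset(phantom_config(size = 32, n_lesions = c(1, 2),
                                         lesion_radius = c(2, 4), seed = 5), 6)

# a slim network and a short memorisation run
cfg <- model_config(stage_channels = c(8, 8, 16, 32, 64),
                    decoder_channels = c(32, 16, 16, 8, 8),
                    channel_reduction = 4)
res <- train_fold(pairs, pairs, model_cfg = cfg,
                  train_cfg = train_config(learning_rate = 1e-2, batch_size = 4,
                                           max_epochs = 60, seed = 3))
glance(res)
evaluate(res$model, pairs)
```

```
# A tibble: 1 × 5
  epochs best_epoch best_dice final_train_loss parameters
   <int>      <int>     <dbl>            <dbl>      <dbl>
1     60         59     0.968           0.0562     497236
Segmentation metrics over 6 slice(s)
  dice         0.968 +/- 0.020
  jaccard      0.939 +/- 0.039
  sensitivity  0.950 +/- 0.034
  specificity  1.000 +/- 0.001
  accuracy     0.998 +/- 0.002
```

The network (497 k parameters at these slim widths; 31.2 M at the default
widths) memorises the six slices: mean Dice 0.97 against the ground-truth
masks, specificity ≈ 1 because almost every background pixel is correctly
rejected despite lesions covering only a few percent of each slice.
`autoplot(res)` shows the loss/Dice trajectories and
`plot_slice_pair(pairs[[1]], predict_prob(res$model, pairs[[1]]$image))`
overlays truth (red) and prediction (cyan).

A command-line interface wraps the same functions:

```sh
Rscript inst/cli/hemoseg generate --n 16 --out data --seed 7
Rscript inst/cli/hemoseg train --config cfg.yaml --epochs 2 --seed 7
Rscript inst/cli/hemoseg summarize
```

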