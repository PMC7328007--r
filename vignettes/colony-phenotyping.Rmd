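---
title: "Quantifying red/white colony phenotypes with platepheno"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying red/white colony phenotypes with platepheno}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Adenine-auxotrophic yeast accumulate a red vacuolar pigment when grown on
limiting-adenine media, while wild-type cells stay white, so colony colour
reads out genetic and epigenetic events colony by colony. The quantity of
interest per plate is the **non-white percentage**,

$$
\mathrm{pct}_{\text{non-white}}
  = 100 \times \frac{n_{\text{red}} + n_{\text{pink}} + n_{\text{variegating}}}
                    {n_{\text{properly segmented}}},
$$

where the denominator counts all properly segmented colonies and excludes
*bad segmentation* regions — connected blobs that actually contain several
small overlapping colonies and cannot be scored as one colony. Scoring
hundreds of plates by eye is slow and irreproducible; `platepheno` automates
it with a two-stage pipeline:

1. **Segmentation.** An encoder-decoder convolutional network assigns each
   pixel a foreground probability. Masks are binarized, border artifacts are
   cleared, morphological opening removes speckle, connected regions are
   measured, and regions are kept only if eccentricity $\le$ 0.6 and
   area $\ge$ 400 px (inclusive thresholds, stated at 1024-px plate
   resolution and scaled quadratically to other working resolutions).
2. **Classification.** Each kept region is cropped (bounding box plus 10%
   padding) and classified into five phenotypes — white, red, pink,
   variegating, bad segmentation — by a small CNN with test-time
   augmentation: the probability vectors of the original crop and four
   randomly augmented copies are averaged. Per-plate class counts and the
   non-white percentage follow.

Because no plate photographs ship with the package, a synthetic plate
generator provides training and evaluation data with pixel-exact ground
truth; every result the package reports is computed on that generator's
output at desk scale (one CPU, minutes).

## The networks and their training

No deep-learning framework is available to this package, and the trainable
stages are its core, so `platepheno` implements a compact CNN engine
directly in R: convolutions as im2col + BLAS matrix products, exact
backpropagation (verified against numerical differentiation in the test
suite), SGD with momentum 0.9 and weight decay 1e-7, and the two cyclical
learning-rate schedules used throughout:

* **circular**: linear rise from `min_lr` to `max_lr` over `epochs_up`
  epochs, linear fall back over `epochs_down`, per cycle;
* **cosine annealing with warm restarts (SGDR)**: each cycle starts at
  `max_lr` and follows a half cosine to `min_lr`, with cycle lengths such as
  `rep(c(1, 2, 4), 17)` — 51 cycles and 119 epochs, the classifier's
  full-scale protocol.

Trainable layers are partitioned into thirds in network order (sizes as
equal as possible, remainder to earlier groups) so that differential
learning rates can be applied per third; "last layer only" phases update
only the output layer. Two architecture families exist for both stages:
`micro` (plain stacks; the segmenter adds U-net-style skip connections via
channel concatenation after nearest-neighbour upsampling) and `resnet_tiny`
(residual blocks in the encoder). Batch normalisation is deliberately
omitted — He initialisation plus biases suffices at these widths, and the
backward pass stays simple and deterministic. Downsampling uses 2x2 average
pooling rather than max pooling so gradients have no tie-breaking
ambiguity. The segmenter's output bias starts at -2.2, the logit of a
rare-foreground prior, because colonies cover well under 10% of a plate and
a zero-initialised bias wastes the first epochs collapsing to background.

Two configuration profiles exist per stage. The `paper` profiles carry the
full-scale protocol this pipeline family uses on real plate photographs
(512- and 1024-px segmentation stages at batch 4; the 50-px, batch-128
classifier with warmup at 1e-2, three 1-epoch cosine cycles, then 17 sets
of (1, 2, 4)-epoch cycles at max rates 1.1e-4/3.3e-4/1e-3); they are kept
for fidelity and config-level tests, but training them requires pretrained
encoders and GPU-scale compute that are out of scope here. The `desk`
profiles are the package's working configuration, sized by pilot runs so
that everything trains in minutes on one CPU:

| parameter | segmenter (desk) | classifier (desk) |
|---|---|---|
| input size | 128 px | 48 px |
| encoder | `micro` (7k params) | `micro` (6k params) |
| batch size | 4 | 64 |
| schedule | last-layer warmup (1 epoch, circular 8e-3..4e-2), then all layers 9 epochs (circular, max 0.08, min 0.004) | warmup 1 epoch at 1e-2 (no augmentation), 3 one-epoch cosine cycles at 1e-2 (head), then one (1, 2, 4) SGDR set over all layers, max rates 0.015/0.015/0.03 |
| loss | BCE with logits (mean; foreground term weighted 3x) | categorical cross-entropy, sqrt-inverse-frequency class weights |
| augmentation | rotation up to 4 deg, horizontal flip, brightness/contrast jitter (geometry shared with the mask, photometric jitter image-only) | rotation up to 10 deg, dihedral-8, brightness/contrast, zoom up to 1.1x |

The segmentation loss weights the foreground term of the binary
cross-entropy by 3 (the `pos_weight` option of this loss family): colonies
cover well under 10% of plate pixels, and with an unweighted loss the
recall of small dark (red) colonies collapses first, which filters them out
downstream and systematically deflates the non-white percentage.

The classifier input is 48 px because variegating colonies are recognised
by their white/red sectors: at 32 px, bilinear downsampling of a large crop
antialiases the sectors into a uniform pink and the class collapses into
`pink`. The class-weighted loss addresses the roughly 40:1 imbalance
between white and bad-segmentation examples; without it the rare class is
never predicted. Early stopping watches validation log loss with a patience
of 3 epochs (the full-scale protocol stops "when over-fitting is observed";
a patience rule is the operational form), and the weights with the best
validation log loss are kept.

## What the synthetic generator emulates

`synth_plate_spec()` fixes the study conditions: a bright agar disk
(tan, RGB 150/125/95) on a dark background, colonies as filled disks with
per-colony multiplicative colour jitter (SD 0.05), an illumination gradient
(amplitude 0.06), additive Gaussian pixel noise (SD 0.02), and optionally a
bright rim ring at the plate edge that resembles foreground — deliberately
present so that the border-clearing step is exercised rather than
decorative. Default colour means are white (230, 225, 210), red
(170, 40, 40), pink (220, 140, 150): separable, but confusable under the
noise model. Default image size is 512 px, configurable; the
end-to-end evaluation uses 128-px plates with ~30 colonies, and colony
radii span 3.2-5% of the image side so that ~30 colonies fit a 128-px
plate without jamming the rejection-sampling placement.

Phenotypes are rendered as their definitions demand: white/red/pink are
single disks (white colonies carry, with probability 0.08, an aged
ring-like morphology — a pinkish annulus around a white centre — a known
hard case that real pipelines misread as pink); variegating colonies have
3-6 alternating white/red angular sectors, each subtending at least
0.35 rad with each colour holding 25-75% of the circumference, because a
colony whose "sectoring" is a 2-degree sliver is white or red by any
reasonable standard, not variegating; bad-segmentation regions are
connected clusters of 2-4 overlapping small disks. Ground truth is
pixel-exact: every colony's footprint is foreground, and the true
non-white percentage follows the same formula as the pipeline's estimate.

What the generator does **not** emulate: agar texture, colony relief and
specular highlights, camera optics and vignetting, colony size-phenotype
correlation (slow-growing silenced colonies are smaller in reality), and
touching colonies beyond the explicit bad-segmentation clusters. Passing
tests on synthetic data therefore demonstrate that the pipeline's machinery
— training, schedules, post-processing, aggregation — is correct and
recovers known ground truth under realistic noise; they do not certify
accuracy on real photographs, which depends on training data the package
does not ship.

## Numerical and design choices

* Coordinates are 0-based and bounding boxes half-open `[min, max)`
  everywhere; region eccentricity is that of the ellipse with the same
  normalized second central moments ($\sqrt{1 - \lambda_2/\lambda_1}$),
  cross-checked against a brute-force per-pixel oracle at 1e-6 relative
  tolerance.
* Connected components use 8-connectivity (diagonally touching blobs are
  one colony). `EBImage::bwlabel` is 4-connected, so diagonal label pairs
  are merged with a union-find.
* Binary erosion/dilation behind `morphological_open()` are implemented as
  vectorized shift-stacks over the exact disk `{(di, dj): di^2 + dj^2 <=
  r^2}` with out-of-image pixels treated as background; the radius defaults
  to 2 px at 1024-px resolution, scaled linearly.
* Mask binarization is inclusive at the threshold (default 0.5, exposed as
  an option); `binarize()` is monotone in the threshold.
* Argmax ties in class probabilities break in the fixed class order white <
  red < pink < variegating < bad_segmentation.
* Test-time augmentation averages probability vectors (not logits) of the
  original plus four augmented copies and renormalizes.
* Plates with no properly segmented colony report an `"undefined"` status
  with `NA` percentage, never 0%, so downstream plate means are not biased.
* Stratified splits use largest-remainder apportionment with ties broken in
  class order; 1476 crops at 20% yield exactly 295 validation crops with
  class proportions preserved to the integer.
* All randomness flows through explicit seeds; datasets derive one child
  seed per item, so item `i` is identical regardless of how many other
  items are generated, and every generator or CLI run with the same seed is
  byte-identical.

## Evaluation sizes

The packaged evaluation (also run by `scripts/acceptance.R`) uses: 1476
crops with class counts 537/273/310/318/38 and a stratified 295-crop
validation split for the classifier; 60 synthetic 128-px plates (48/12
train/validation) for the segmenter; 1000 plate-scale crops for the
pipeline's classifier; and 20 test plates with true non-white percentages
spaced across 0-100%. These sizes keep every training run in the
single-digit minutes on one CPU while leaving the learning problems
non-trivial. The classifier for the end-to-end run is trained separately
from the 512-px-scale classifier because the pipeline's crops come from
128-px plates; matching the training distribution to the prediction
distribution is part of the method, not a convenience.

## Known limitations

* The `paper` profiles are configuration-faithful but not trainable here:
  ImageNet-pretrained ResNet-34 encoders are not distributable inside this
  package and random-init networks of that size need GPU-scale compute.
* The CNN engine is CPU-bound R; it is sized for desk-scale work, not for
  1024-px production segmentation.
* Touching colonies are filtered out (by eccentricity/area or as
  bad-segmentation predictions), not split; plates dominated by merged
  colonies will report on a minority of their colonies.
* Synthetic realism bounds what the packaged accuracies mean for real
  plates (see above); retraining on real labelled crops uses the same
  functions unchanged.
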