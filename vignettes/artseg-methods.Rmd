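---
title: "Weakly supervised artifact segmentation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weakly supervised artifact segmentation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Brightfield images from high-content screens are routinely contaminated by
foreign objects — dust, fibres, hair, out-of-focus debris, cell clumps.
These artifacts corrupt everything computed downstream of segmentation:
nuclei counts, morphometry, fluorescence quantification and the
pharmacological parameters regressed from it. Annotating artifacts
pixel-by-pixel is expensive; flagging whole images as *clean* or
*artifact-containing* is cheap. `artseg` turns those cheap image-level
labels into a pixel-level artifact segmenter.

## The ScoreCAM-U-Net scheme

Training proceeds in five stages:

1. **Classifier.** A small residual CNN is trained to separate clean from
   artifact-containing images with binary cross-entropy.
2. **Score-CAM.** For every artifact-labeled training image, a saliency
   map is computed from the classifier by forward passes only: the
   activation maps $A_k$ of the last convolutional layer are upscaled to
   input size (bilinear) and min-max normalized to $[0,1]$; each
   normalized map $\hat A_k$ multiplies a copy of the (normalized) input,
   and the classifier scores each projected image, giving per-map weights
   $w_k$; the saliency map is
   $\mathrm{minmax}\!\left(\mathrm{ReLU}\!\left(\sum_k w_k \hat A_k\right)\right)$.
3. **Threshold selection.** The saliency maps are binarized at the grid
   threshold maximizing mean pixel IoU against validation masks when pixel
   ground truth exists for the validation split; otherwise the default
   0.05 applies. Ties break toward the smaller threshold.
4. **Pseudo-labels.** Artifact-labeled images receive their binarized
   saliency map; clean-labeled images receive all-zero masks, so the
   segmenter also sees negative supervision.
5. **U-Net.** An encoder-decoder segmenter is trained on the pseudo-labels
   with pixel-wise binary cross-entropy.

At inference the classifier acts as a gate: images whose artifact
probability does not exceed 0.5 get an empty mask; all others are
segmented by the U-Net, binarized, and cleaned of small connected
components.

The full-scale U-Net preset has 15 encoder and 15 decoder convolutional
layers (3×3, ReLU), a 2×2 max-pool and skip connection after every third
encoder layer, ×2 nearest-neighbour upsampling after every third decoder
layer, a 3-layer bottleneck, and 64 filters per layer; the output head is
a 1×1 convolution with sigmoid. The small preset used throughout the
tests keeps the every-third-layer motif at test scale: 6+6 encoder/decoder
layers, 2 bottleneck layers, 16 filters, 2 pooling stages (inputs must be
divisible by 4; full preset, by 32). Inputs that are not divisible are
reflect-padded and the prediction cropped back.

## Design choices in the classifier

Several details of the classification backbone are open design territory,
and two choices here departed from the obvious defaults after reference
runs on synthetic data:

* **Global max pooling head.** Artifacts are spatially sparse — often a
  few percent of the field. Global *average* pooling dilutes the texture
  signal by the inverse of its area fraction, and a three-stage CNN under
  a 10-epoch desk-scale budget never escaped chance-level loss with it.
  Global *max* pooling keeps the strongest local response per feature map
  and separates the classes within a few epochs at the default learning
  rate. Score-CAM is unaffected by the head choice: it only needs the
  activation stack and the class probabilities.
* **Input standardization.** Images are min-max scaled to $[0,1]$ (so 8-
  and 16-bit inputs coexist) and then standardized per image to zero mean
  and unit variance. Without batch normalization layers, standardized
  inputs keep early-layer activations well scaled. The Score-CAM
  projection multiplies the normalized map with this standardized input;
  masked-out regions thus sit at the per-image mean rather than at black.
* **Score-CAM weights.** Each projected input is scored for the
  *artifact* class — the target class, not the maximum over classes:
  pseudo-labels must localize the artifact class specifically. The
  per-map weights are these target-class scores softmax-normalized
  *across* the activation maps, as in the Score-CAM framework (a constant
  baseline score cancels inside the softmax). The normalization matters:
  a well-trained classifier still recognizes the artifact in almost every
  projected input, so raw probabilities weight every map near 1 and the
  saliency dissolves into "everything that activates anywhere";
  normalizing across maps concentrates weight on the few maps whose
  projection is most artifact-evoking.
* **CAM resolution.** The last residual stage runs at half input
  resolution rather than a quarter (pooling after stages 1 and 3 only),
  so the activation stack is 48×48 for 96-px inputs. Artifacts of 10–20
  px cannot be outlined by a 24×24 map; doubling the stack resolution
  raised pseudo-label IoU by ~0.1 on the reference runs.

Training defaults mirror the published procedure: Adam, initial learning
rate 0.002, reduced tenfold when the validation loss has not improved for
10 consecutive epochs, 150 epochs, binary cross-entropy; batch size 16
(not stated in the original procedure; configurable). Desk-scale
reference runs use 10 epochs or fewer with patience scaled down
accordingly and batch size 4 — a 120-image training split at batch 16
yields only ~80 Adam steps in 10 epochs, too few to converge either
network — and learning rate 0.005 for the segmenter, whose per-pixel loss
surface tolerates (and, under a 10-epoch budget, needs) a faster rate
than the classifier. The U-Net input is normalized exactly like the
classifier input (min-max then per-image standardization).

## Binarization cutoffs

Two distinct constants co-exist deliberately. The *pseudo-label* cutoff
(default 0.05) binarizes saliency maps for U-Net training. The
*evaluation* cutoffs (0.001 for Score-CAM and ScoreCAM-U-Net probability
maps, 0.45 for the strongly supervised U-Net) binarize probability maps at
inference; they were selected on full-scale validation data and are wired
into `postprocess_config()` as preset constants, together with the
published minimum object sizes (1000 px for the seven-cell-lines preset,
500 px for the CHO-M4R and LNCaP presets). Because such cutoffs are
dataset-dependent — they were chosen to maximize validation IoU — the
orchestrated pipeline (`run_full_training()`) re-selects the evaluation
cutoff on its own validation probability maps whenever pixel ground truth
is available, and reports it as `eval_cutoff`. Whether probability maps
should be re-normalized before applying a published cutoff is not
specified by the original procedure; here U-Net probability maps are used
as the sigmoid emits them, and saliency maps are min-max normalized as
part of their construction.

## Clean-image synthesis

For screens where nearly every field contains an artifact, clean
counterparts are synthesized rather than found: a two-dimensional
second-order polynomial $b(x,y) = c_0 + c_1 x + c_2 y + c_3 x^2 +
c_4 x y + c_5 y^2$ is least-squares fitted to the image, a zero-centered
noise profile is taken from the background-pixel residuals, and annotated
artifact pixels are replaced by $b(x,y)$ plus a draw from the noise pool.
Three details are the package's own choices: coordinates are normalized to
$[-1,1]$ before fitting (raw pixel indices in the thousands make the
normal equations ill-conditioned); artifact pixels are excluded from the
fit (a bright or dark artifact would otherwise bias the surface it is
about to be replaced with); and noise is resampled with replacement from
the empirical residual pool rather than from a fitted Gaussian, preserving
non-Gaussian tails. When a nuclei mask is supplied, nucleus pixels are
also kept out of the noise pool.

## Evaluation metrics

Pixel-wise precision, recall, F1 (harmonic mean) and IoU
($tp/(tp+fp+fn)$) are computed from confusion counts; image-level F1
treats *artifact* as the positive class. Object-wise F1 extracts
connected components from both masks (8-connected by default), matches
them one-to-one greedily by descending pairwise IoU, and counts a match as
a true positive iff its IoU reaches 0.5 — the matching rule is
configurable because the published evaluation defers it to prior work.
Undefined ratios (e.g. precision with no predicted positives) are reported
as `NA`, never as 0, and per-image averaging skips them; pooled-count
aggregation is also available. Dataset-level results default to per-image
averaging; precision-recall curves pool pixels across images and integrate
precision over recall trapezoidally.

## Downstream analyses

*Stratified nuclei scoring* computes pixel metrics inside and outside the
artifact region separately (counts over the two disjoint regions add up
exactly to the whole-image counts) and assigns objects to a region by
majority pixel overlap, ties to inside. *Morphometry* reports per-nucleus
area and solidity; solidity is area over the exact (shoelace) area of the
convex hull of the pixel corners — a rasterized hull was rejected because
pixel centers landing exactly on hull edges made the discrete area
float-order-dependent.

*Ligand affinity*: per image, specific fluorescence is the mean over
cell-and-not-artifact pixels minus the mean over background
(non-cell, non-artifact) pixels; per well, the per-image values are
averaged. Concentration-response curves are fitted with the Hill equation
with slope fixed at −1,
$Y = \mathrm{Bottom} + (\mathrm{Top}-\mathrm{Bottom})/(1+10^{X-\mathrm{LogIC50}})$,
$X = \log_{10}$ concentration, by Levenberg-Marquardt least squares
(`minpack.lm`), started from the response extremes and the concentration
nearest the midpoint. The reported SD of LogIC50 is the asymptotic
(covariance-based) estimate — the commercial tool used in the original
analysis does not document its estimator, so the standard asymptotic one
is implemented and labeled as such. $R^2 = 1 - SS_{res}/SS_{tot}$.
Removal strategies are compared by mean |ΔLogIC50|, per-curve $R^2$, and
the Pearson correlation of paired well intensities.

## The synthetic data generator

Every quantitative claim in the test suite runs on synthetic fields with
exact ground truth. A field is a second-order polynomial illumination
surface (the same family the cleaner fits, deliberately), plus nuclei
drawn as soft-edged dark disks, plus artifacts, plus i.i.d. Gaussian
noise; intensities live on a 16-bit-like scale (default background level
~30 000, noise sd 300). Artifacts span the size/shape heterogeneity of
real screens with three families: filled ellipses with speckle texture
(semi-axes ~6-18 px at 96×96), fibre/hair curves rasterized from random
walks and dilated to 2-5 px width, and clumps formed as unions of
overlapping disks; contrasts are ±7 000-12 000 against the local
background. An image is labeled *artifact* iff its mask has at least one
positive pixel. Plates assign wells to log-spaced concentrations
(duplicate wells per concentration, two fields per well by default); the
fluorescence channel is a flat background plus, inside cell pixels, the
Hill response for the well's concentration, so the generative LogIC50 is
exactly recoverable by construction; injected artifacts add a strong
aberrant offset (4×dynamic range) inside their pixels.

What the generator does *not* emulate: optics (no point-spread function,
no defocus), cell-type-specific morphology, spatially correlated noise,
artifact classes beyond the three families, or the blurry artifact borders
of real images. Passing tests therefore demonstrate that the pipeline's
machinery is correct and that weak supervision distills localization into
segmentation under controlled conditions — not that full-scale benchmark
numbers on real microscopy data are reproduced.

## Problem sizes and numerical choices

Tests and the acceptance script run at desk scale as the package's own
reference conditions: 200 images of 96×96 at 50% artifact prevalence
(split 0.6/0.2/0.2), small model presets, at most 10 epochs per stage,
batch size 4; the downstream experiment uses 20 replicate plates of 8
concentrations in duplicate at 48×48 with 50% artifact rate; Hill
recovery uses 50 plates with pixel noise at 5% of the top asymptote.
Determinism: every public generator and training routine threads one
integer seed through data order, initialization and augmentation-free
training; child seeds derive from the master by a fixed affine map modulo
2^31−1. Constant saliency or activation maps min-max normalize to zero
(no localization signal); max pooling breaks ties toward the first
position in raster order; small-object removal deletes components
*strictly* below the minimum size; map binarization is strictly greater
than the threshold.

## Known limitations

The classifier's "full" preset is a scaled-up residual CNN, not a
faithful ResNet50, and no pretrained weights are used; at full image
scale (1080×1080) training this implementation is CPU-bound and untested.
Pseudo-label quality depends on how discriminative the artifact texture
is for the classifier; on data where artifacts resemble cells the CAM
blobs will be diffuse and the selected pseudo-label threshold only
partially compensates. The Hill model is restricted to slope −1 (no
variable-slope or biphasic fits), and IC50 is not converted to binding
constants.
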