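# artseg

Weakly supervised segmentation of imaging artifacts — dust, fibres, hair,
debris, clumps — in brightfield cell-microscopy images, using only
image-level *clean* / *artifact* labels.

High-content screens produce thousands of fields of view; artifacts in
them corrupt nuclei counts, morphometry and intensity-based readouts such
as ligand-binding curves. Pixel-level artifact annotation is too expensive
to scale, but flagging whole images is fast. `artseg` implements the
**ScoreCAM-U-Net** scheme, which turns image-level labels into a
pixel-level segmenter:

1. train a CNN classifier on the clean/artifact labels;
2. explain it with **Score-CAM**: activation maps \(A_k\) of the last
   convolutional layer are upscaled, min-max normalized to \(\hat A_k\),
   projected onto the input by multiplication, and re-scored by the
   classifier to give per-map weights \(w_k\); the saliency map is
   \(\mathrm{minmax}(\mathrm{ReLU}(\sum_k w_k \hat A_k))\);
3. binarize the saliency maps (threshold selected by validation IoU,
   default 0.05) into **pseudo-labels**;
4. train a **U-Net** on the pseudo-labels with pixel-wise binary
   cross-entropy;
5. at inference, classify first (gate at artifact probability 0.5), then
   segment, binarize and remove small objects.

The package also provides: clean-image synthesis (second-order 2-D
polynomial background fit + zero-centered noise-profile inpainting), the
full evaluation suite (pixel / object / image-level precision, recall,
F1, IoU, PR curves), a synthetic brightfield data generator with exact
ground truth, and the downstream impact analyses: artifact-stratified
nuclei scoring, nucleus morphometry (area, solidity), artifact-excluded
fluorescence quantification, and Hill-equation concentration-response
regression (slope fixed at −1),

\[ Y = \mathrm{Bottom} + \frac{\mathrm{Top}-\mathrm{Bottom}}{1+10^{\,X-\mathrm{LogIC50}}},
   \qquad X = \log_{10}[\text{ligand}] . \]

All networks run on a compact, dependency-free CNN engine (batched 3×3
convolutions with Rcpp inner kernels, Adam, plateau learning-rate
schedule); no GPU or deep-learning framework is required.

## Worked example

Generate a labeled synthetic dataset, run the full weakly supervised
pipeline, and evaluate on the held-out test split:

```r
library(artseg)

ds   <- generate_dataset(100, 0.5, field_spec(96, 96), c(0.6, 0.2, 0.2), seed = 301)
imgs <- lapply(ds$fields, `[[`, "image")
gts  <- lapply(ds$fields, `[[`, "artifact_mask")

run <- run_full_training(
  imgs, ds$labels, ds$split, gt_masks = gts,
  classifier_cfg = classifier_config("small"),
  unet_cfg       = unet_config("small"),
  train_cfg      = train_config(epochs = 8, lr_patience_epochs = 4, batch_size = 4),
  segmenter_train_cfg = train_config(initial_learning_rate = 0.005, epochs = 8,
                                     lr_patience_epochs = 4, batch_size = 4),
  seed = 19)

te <- which(ds$split == "test")
pred <- vapply(te, function(i)
  ifelse(classify(run$classifier, imgs[[i]])[1, "artifact"] > 0.5,
         "artifact", "clean"), character(1))
image_level_f1(pred, ds$labels[te])

post <- postprocess_config("scorecam_unet",
                           binarization_cutoff = run$eval_cutoff,
                           min_object_size = 30)
reports <- lapply(te, function(i) {
  mask <- predict_artifacts(imgs[[i]], run$classifier, run$segmenter, post)
  pixel_metrics(mask, gts[[i]])
})
round(aggregate_metrics(reports)$per_image_mean, 3)
```

Output (about 8 minutes on one CPU):

```
image-level metrics (tp=9 fp=0 fn=0): precision=1.0000 recall=1.0000 f1=1.0000 iou=1.0000
precision    recall        f1       iou
    0.599     0.887     0.696     0.542
```

The image-level report says the classifier gate recovered all 9
artifact-containing test images with no false alarms. The aggregated
pixel-level report scores the predicted masks against ground truth over
the 20-image test split: 89% of true artifact pixels are found at 60%
precision (mean per-image IoU 0.54) — the segmenter localizes artifacts
without ever having seen a pixel label. `run$threshold` holds the
pseudo-label cutoff selected on validation saliency maps (here 0.3) and
`run$eval_cutoff` the evaluation-time binarization cutoff selected the
same way (here 0.4).

Affinity estimation from a synthetic concentration-response plate:

```r
assay <- assay_spec(logIC50_true = -7, noise_sd = 30, artifact_rate = 0.5, seed = 7)
plate <- generate_plate(assay, field_spec(48, 48, nucleus_count = 6,
                                          nucleus_radius_range = c(3, 5)))
wells_rm <- well_specific_intensity(plate$images)                   # artifacts removed
wells_no <- well_specific_intensity(plate$images, use_artifact_masks = FALSE)
fit_hill(wells_rm$concentration_M, wells_rm$specific_intensity)
fit_hill(wells_no$concentration_M, wells_no$specific_intensity)
```

```
Hill fit (slope -1): LogIC50 = -7.001 +/- 0.002, Top = 1000.7, Bottom = 99.8, R2 = 1.0000
Hill fit (slope -1): LogIC50 = -7.189 +/- 0.408, Top = 951.8, Bottom = 110.3, R2 = 0.6954
```

With artifact pixels excluded the fit recovers the generative LogIC50 of
−7 almost exactly; ignoring the artifacts shifts the estimate by ~0.19
log units, inflates its standard deviation two-hundred-fold and drops
the explained variance to 0.70.

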