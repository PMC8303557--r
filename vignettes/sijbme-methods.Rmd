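---
title: "Detecting sacroiliac bone marrow edema on MR slices: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting sacroiliac bone marrow edema on MR slices: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Active sacroiliitis — the inflammatory stage of axial spondyloarthritis
(axSpA) — manifests as bone marrow edema (BME) in the sacroiliac joints
(SIJ): hyperintense signal adjacent to the joint line on gadolinium-enhanced
fat-suppressed T1-weighted oblique-coronal MR slices. Reading these studies
is slow and inter-reader agreement is moderate, which makes the task a
natural target for automated slice-level detection followed by a
subject-level diagnostic decision.

`sijbme` implements that pipeline end to end:

1. **ROI patch construction.** From manually annotated bounding boxes of the
   left and right iliac bones, a region of interest per side is shifted
   medially towards the sacrum so that it covers the joint space and the
   near half of the sacrum — the region where BME occurs. The two crops are
   height-matched and concatenated into a single patch, which is resized
   (bilinearly) to the classifier input.
2. **Scanner-noise injection.** A Gaussian + Poisson noise model is applied
   to every image identically, regardless of later train/validation/test
   membership, to emulate Rician acquisition noise and harden the classifier
   against scanner variation.
3. **Slice classification.** A convolutional network with a residual
   backbone, one hidden fully connected layer and a sigmoid output scores
   each slice for BME. Training uses the focal loss, batch normalization,
   SGD with momentum under a cosine learning-rate schedule, and
   horizontal-flip/rotation augmentation (never random crops, which can cut
   off the lesion).
4. **Contextual correction.** Per subject, the ordered slice decisions
   (lower to upper pelvis) are filtered with a size-3 one-dimensional median
   filter: adjacent slices image adjacent anatomy, so isolated positives are
   treated as errors and single gaps inside positive runs are restored.
5. **Subject diagnosis.** The filtered decision vector is aggregated into a
   per-subject diagnosis; metrics are evaluated over repeated subject-wise
   stratified 70/30 splits and reported as mean ± standard deviation,
   together with the slice-level ROC AUC.
6. **Explanation.** Grad-CAM saliency maps over the last convolutional stage
   visualize which image region drove a positive classification.

Clinical MR data of this kind is not publicly available, so the package
ships a synthetic phantom generator that stands in for it everywhere —
tests, examples, and the acceptance script all run on phantoms.

## The ASAS positivity rule

A subject is labeled positive for active sacroiliitis when there are at
least two BME lesions on a single slice, or BME on at least two consecutive
slices (`asas_label()`). The default subject decision rule (`any_positive`
after a size-3 median filter) mirrors this: a positive survives the filter
exactly when some window of three consecutive slices contains at least two
positives — adjacent pairs, interior 1-0-1 patterns, or a replicate-padded
boundary positive. It is maximally sensitive, which matches the intent of a
screening aid. A `mean_threshold` rule (positive when the mean filtered
decision exceeds `tau`) is provided as the literal "averaging" alternative;
with `tau = 0` the two coincide.

## ROI geometry

The published description of the ROI construction is partly pictorial, so
the package fixes a concrete rule: for an iliac box spanning columns
`[a, b)` of width `W`, the ROI spans `floor(0.8 * W)` columns medially from
the box center, with the iliac box's rows. The right side mirrors the
construction, using the mirror-consistent center `ceil((a' + b') / 2) - 1`
so that reflecting the annotations about the image midline maps one ROI
exactly onto the other. The shift fraction (default 0.8) is a configuration
knob. If the two crops differ in height, the shorter one is extended
symmetrically with source-image rows — never interpolated — before the
left and right crops are concatenated.

On phantoms this geometry is validated directly: at least 95% of lesion
pixels must fall inside the union of the two ROIs across random positive
slices.

## Noise model

The noise model follows the published description: zero-mean Gaussian noise
with variance 0.3, plus a Poisson component whose mean is set per image by
drawing one pixel value `p` uniformly at random and taking
`lambda = log(255 * p + 1)^4` on the 8-bit scale; one Poisson deviate per
pixel is added after rescaling by 1/255. Both defaults are kept in
`noise_params()` for fidelity, but on `[0,1]` intensities they are
destructive once the output is clipped (variance 0.3 means a noise standard
deviation of ~0.55 — larger than the full dynamic range — and typical
`lambda` values are in the hundreds). The intensity scale on which the
published values were applied is not stated. The pipeline presets therefore
use mild Gaussian noise (variance 0.01) with the Poisson component disabled;
Monte-Carlo tests of the Poisson rule run with clipping off, where its mean
and the Gaussian variance can be verified against theory.

## Classifier and training protocol

Three backbones are available. `resnet18` is the five-stage residual
network: a 7x7/64 stride-2 stem, four stages of two basic (3x3-3x3)
residual blocks with projection shortcuts at stage transitions, giving the
conventional count of 18 weighted layers. `resnet50` follows the same stem
and stage-2 basic blocks, with 1x1-3x3-1x1 bottleneck blocks from the third
stage on. `tiny` is a three-block convolutional network (8, 16, 32 channels,
each block conv-BN-ReLU-maxpool) for CPU-scale experiments; the whole
pipeline runs on it in minutes. All heads are identical: global average
pooling, one hidden fully connected layer (width 64 by default), and a
sigmoid output with one node per class (`two_node`) or a single positive
logit (`single_logit`). The two-node-with-sigmoid head is unusual but kept
as described; the single-logit mode is the conventional equivalent.

Training uses the focal loss `FL(p) = -alpha (1-p)^gamma log p` (defaults
`alpha = 0.25`, `gamma = 2` from the original focal-loss work; the published
study does not state them), batch size 32, SGD with momentum 0.9, and the
cosine schedule `lr(t) = lr_min + (lr0 - lr_min)(1 + cos(pi t / T)) / 2`.
The decision threshold on the sigmoid score is 0.5; the published work does
not state one.

Transfer learning (`pretrained = TRUE`) loads backbone weights from a
user-supplied file; ImageNet weights are not bundled (they are large binary
artifacts), so from-scratch training is the default everywhere in this
package.

Two numerical choices matter for from-scratch CPU-scale training:

* **Per-dataset standardization.** Patch intensities are standardized with
  the training set's mean and standard deviation, stored on the classifier
  and applied to every later input (the backbone-statistics variant would
  apply only with pretrained weights).
* **Batch-norm recalibration.** Augmented training batches bias the
  batch-norm running statistics relative to the un-augmented inputs seen at
  evaluation time. After the last epoch the running statistics are recomputed
  over the un-augmented training data (momentum `1/k` over batches `k`,
  which yields the plain average of per-batch statistics). Without this the
  evaluation-mode score distribution shifts and the 0.5 threshold
  miscalibrates even when the ranking (AUC) is essentially perfect.

The reference protocol's initial learning rate (0.03) and epoch budget (50)
are the `classifier_config()` defaults, matching the published protocol for
the residual backbones. The tiny-backbone presets used by the bundled
experiments (`default_run_config()`, the test suite, and the acceptance
script) train for 15 epochs at an initial rate of 0.15: a from-scratch
three-block network on a few hundred patches sees far fewer gradient updates
than a fine-tuned 18-layer network on hundreds of thousands of augmented
crops, and the focal loss further shrinks early gradients by roughly
`alpha * (1-p)^gamma ~ 1/16` relative to cross-entropy near `p = 0.5`.

## The phantom generator

`phantom_params()` / `generate_subject()` / `generate_cohort()` emulate the
study conditions the pipeline expects:

* Two bright lateral iliac ellipses flank a central, slightly darker sacrum,
  separated by dark joint lines; bone size varies smoothly along the stack.
* Negative (normal) subjects contribute 18–25 clean slices.
* Positive subjects contribute 4–23 lesioned slices — mirroring the
  reference labeling rule in which only clearly lesioned slices of patients
  enter the dataset, so every used patient slice is a positive sample. Each
  exam has one inflammation site adjacent to a joint line whose center
  drifts by at most ~2 px between adjacent slices (so slice predictions form
  realistic runs for the median filter), and some exams carry a bilateral
  slice with two lesions. Every positive exam satisfies the ASAS rule.
* Lesions are disks of radius 2–4 px at intensity `bone + lesion_contrast`
  (default contrast 0.35 on `[0,1]`), placed at the medial iliac margin so
  they fall inside the computed ROIs.
* Rician-like acquisition noise (`sqrt((I + s g1)^2 + (s g2)^2)`,
  `s = 0.02`) is applied to every slice.

The published study does not quantify lesion size or contrast
distributions; these parameters are chosen once as plausible for
contrast-enhanced BME (conspicuous, compact, joint-adjacent lesions) and are
knobs of the generator, not estimates of the clinical data. What passing
tests on phantoms show is that the pipeline's machinery — geometry,
training, filtering, aggregation, explanation — recovers a planted signal
whose structure matches the labeling rules; they say nothing about
performance on real MR data, where lesions are atypical in shape, contrast
varies, and anatomy interferes (the published Grad-CAM failure case, bright
sacral bone structure attracting the network, is exactly such an effect).

Problem sizes in the bundled experiments are phantom-scale by design: the
test suite and the acceptance script train the tiny backbone on a
20-subject cohort (roughly 350 slices) with 1–3 repeated splits, while unit
tests use 2–6 subjects. The full-size protocol (60 + 19 subjects, five
repeats, residual backbones at 224x224) is expressed by the same functions
with larger arguments.

## Evaluation

`metrics_from_confusion()` reports accuracy, recall, precision, specificity,
NPV and F1 as percentages. NPV is `TN / (TN + FN)` — the published metric
list gives NPV the same verbal description as specificity (an apparent
duplication), and the standard definition is the one consistent with the
reported subject-level table, where zero false negatives force recall and
NPV to 100 simultaneously. Metrics with zero denominators are reported as
missing rather than zero, so fold averages are not silently deflated. AUC is
the midrank Mann–Whitney statistic, identical to the trapezoidal area under
the empirical ROC curve; ties count one half. Fold summaries use the sample
standard deviation (0, flagged, for a single fold). Note that the average of
per-fold F1 values is not the F1 of averaged precision and recall; the
per-fold table keeps both ingredients.

Splits are drawn per repeat at the subject level, stratified by class
(`round(0.7 * n)` subjects of each class to training), so slices of one
subject never straddle the train/test boundary.

## Degenerate inputs and tie-breaks

* Empty prediction sequences, empty confusion tables and single-class ROC
  inputs are errors, not silent defaults.
* `median_filter_1d` uses replicate padding: a boundary positive survives a
  size-3 filter, which never converts a genuine two-slice boundary run into
  zeros. The filter is a fixed point on sequences whose runs all reach the
  window size.
* Grad-CAM maps are max-normalized per map; an all-zero map (no positive
  evidence at the target class) stays all-zero. Upsampling is bilinear.
* Box coordinates are 0-based, half-open, row-major everywhere; conversion
  to R's 1-based indexing happens only at the crop.

## Known limitations

* No automatic iliac-bone detection or sacrum/ilium segmentation: bounding
  boxes are inputs (annotations in clinical use, ground truth from the
  generator on phantoms).
* The CNN engine is deliberately minimal (direct + im2col/BLAS kernels,
  single-threaded): adequate for phantom-scale experiments and exact
  gradient checks, but not a GPU-scale training stack.
* Phantom realism is limited to what the pipeline exercises; there is no MR
  physics (k-space, bias fields, partial volume).
* Detection of other SIJ lesion types (synovitis, enthesitis, capsulitis,
  structural change) is out of scope.
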