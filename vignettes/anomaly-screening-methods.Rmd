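---
title: "Explainable anomaly detection for breast-MRI screening MIPs: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Explainable anomaly detection for breast-MRI screening MIPs: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Breast-MRI screening of high-risk women finds cancer in only a small
fraction of examinations, so a clinically useful detector must work at low
prevalence and must show *where* it believes a malignancy is.  `mipanomaly`
implements a one-class (anomaly detection) approach to this problem on
two-dimensional subtraction maximum-intensity projections (MIPs): each
unilateral breast image receives a pixelwise anomaly map whose mean is the
breast-level malignancy score, so the explanation *is* the score rather
than a post-hoc saliency estimate.

## Models

All four objectives share one small fully convolutional backbone
`phi(X)` — by default four 3x3 convolution layers (16/32/64/128 channels,
stride-2 downsampling twice, cumulative stride $s = 4$, receptive field
$r = 13$ px, no global pooling), producing a $d \times u \times v$ feature
map.

**FCDD (fully convolutional data description).**  The pixelwise anomaly
score is the pseudo-Huber distance of each spatial feature vector from the
origin (the hypersphere centre),
$$A_{ij} = \sqrt{\lVert \phi_{\cdot ij} \rVert^2 + 1} - 1,$$
and the breast-level score is the mean $s(X) = \frac{1}{uv}\sum_{ij} A_{ij}$.
Training minimises the semisupervised one-class loss
$$\ell = (1 - y)\, s(X) - y \log\!\big(1 - e^{-s(X)}\big),$$
which pulls benign (nominal) images toward the centre and pushes labelled
malignancies away.  Benign-only training is supported — the $y = 1$ branch
is simply absent.  The heat map needs no secondary interpretability
technique: the low-resolution map is upsampled with a fixed Gaussian
kernel (below).

**FCDD-Symmetric.**  Breasts are roughly mirror-symmetric, so the
contralateral breast can serve as a patient-specific normal reference:
$A_{ij} = \sqrt{\lVert \phi^{ipsi}_{\cdot ij} - \phi^{contra}_{\cdot ij}
\rVert^2 + 1} - 1$.  Gradients flow through both branches of the shared
backbone; this is the simplest faithful reading of "contralateral breast as
the normal class centre" (the alternative — freezing the contralateral
branch — would break the symmetry of the learning signal for no clear
gain).

**HSC (hypersphere classification).**  The same pseudo-Huber objective
applied to the globally pooled embedding; a strong anomaly detector but
not spatially explainable by itself, hence the Grad-CAM comparator below.

**BCE.**  A conventional classifier: global average pooling, a linear
head, sigmoid cross-entropy.  This is the binary-classification baseline
that anomaly detection is compared against.

## Explanations

FCDD's native explanation is a transposed convolution of the
low-resolution map with a fixed, non-learned Gaussian kernel of size $r$
(the receptive field) and stride $s$, $\sigma = r/4$ by default: each grid
cell deposits its score as a bump centred on its receptive-field centre.
The operation is linear, preserves nonnegativity, and conserves total mass
except at image boundaries.  For BCE and HSC we provide Grad-CAM (channel
weights = spatially pooled gradients of the logit / pooled anomaly score;
ReLU of the weighted activation sum; bilinear upsampling), defaulting to
the last convolutional layer.

Heat maps are normalized for display either *locally* (each map min-max
scaled on its own, for comparing models on one breast) or *globally* (one
min/max across the evaluated set, for comparing cases under one model);
global normalization uses the evaluated set, not the training set.
Spatial agreement with a truth mask is quantified by pixelwise AUC — the
rank (Mann-Whitney) AUC of map values against abnormal/normal pixel
labels, ties counted one half.  Because the statistic is rank-based it is
invariant under monotone transforms, so the normalization mode cannot
change it.  Benign images (empty masks) have undefined pixelwise AUC and
are excluded from explainability summaries, matching a malignant-only
explanation test set.

## Evaluation protocol

Two screening tasks are evaluated from one cohort: *balanced* detection
(all images; around 20% malignant) and *imbalanced* detection, which
excludes images flagged as known cancer from every **test** fold (a known
cancer would not be screened) while retaining them for training — leaving
roughly 1.85% test prevalence under the generator defaults.  Folds are
grouped by patient; no patient contributes to both sides of a fold.

Per (model, task, fold, seed) cell we report AUC, AUPR (average-precision
convention, whose chance level equals the prevalence — the natural
baseline in imbalanced screening), and three operating points: the Youden
maximiser (ties broken toward higher specificity, the conservative call in
screening) and the largest thresholds achieving at least 95% and 97%
sensitivity (the constraint is met, never approximated; specificity is
monotone in the target).  Aggregates are means ± SD over exactly the
folds-by-seeds cells; model pairs are compared with the two-sided Wilcoxon
signed-rank test, pairing cells by (fold, seed), zeros dropped, exact null
for up to 25 untied differences and the tie-corrected normal approximation
otherwise.  Percentile bootstrap CIs resample at the breast level by
default (the unit of analysis is the unilateral breast) with a
patient-level option acknowledging within-patient clustering; raw
empirical PPV is reported without prevalence adjustment.

## The phantom generator

No clinical images ship with the package, so every stage is exercised on
synthetic bilateral phantoms that reproduce the statistical structure the
method exploits, not the appearance of real MIPs:

* a half-ellipse breast on a dark background (chest wall at the left edge
  in the canonical orientation);
* background parenchymal enhancement (BPE) texture: a low-pass Gaussian
  random field whose amplitude increases over the four BPE categories
  (0.05 / 0.09 / 0.14 / 0.22 on the unit intensity scale, drawn per
  patient with probabilities 0.43 / 0.30 / 0.17 / 0.10) on a 0.15 base
  enhancement level — BPE is the principal confounder, and the stratified
  reports show the expected performance drop at higher BPE;
* bilateral correlation: the two breasts of an exam share a common field
  with weight `rho = 0.8` (an independent field enters with weight
  `sqrt(1 - rho^2)`), so the mirrored pair correlates at `rho` — the
  structure FCDD-Symmetric relies on;
* lesions: *masses* are anisotropic Gaussian bumps (half-max radius 4–10 px
  at the 128x128 reference frame, contrast 0.25–0.55) whose truth mask is
  the above-half-max ellipse; *NME* (nonmass enhancement) is a thresholded
  mid-frequency noise patch — irregular, possibly multi-lobed, lower
  contrast (0.10–0.22) — mixed 60/40 with masses.  Truth masks are
  geometric, so a zero-contrast lesion keeps a nonempty mask;
* cohort structure: 1–3 exams per patient (mean 1.8), at most one
  malignant breast per exam (bilateral synchronous cancers are out of
  scope), breast-level prevalence binomial around the configured rate, and
  an exam-level known-cancer flag on 94% of malignant exams, calibrated so
  that removing known-cancer exams from a 20%-prevalence cohort leaves
  about 1.85% — the imbalanced screening condition;
* a lesion-size bin (`stage_proxy`) cut from mask area at 160/280/430 px²
  (reference frame), yielding more small than large lesions.  Pathological
  T stage has no phantom analogue; mask area is the only available proxy.

Lesion geometry scales linearly (areas quadratically) with image size, so
cohorts rendered below 128x128 keep the same relative lesion load.

What phantoms do **not** emulate: MR physics and reconstruction, motion
and bias-field artifacts, chest-wall/axillary structures, multi-focal
disease beyond NME lobes, and the visual heterogeneity of real parenchyma.
Passing phantom tests therefore demonstrates that the implementation is
correct and that the method behaves as designed under its own assumptions;
it does not certify clinical performance.

## Numerical and design choices

* **Loss guard.**  $\log(1 - e^{-s})$ diverges at $s = 0$; we clamp
  $e^{-s} \le 1 - \varepsilon$ with $\varepsilon = 10^{-6}$, bounding the
  anomalous branch by $-\log \varepsilon$.  Global gradient-norm clipping
  (default 5) tames the steep gradient of that branch when an anomaly
  scores near zero.
* **One-class (benign-only) training.**  With no labelled anomalies the
  zero-centre objective has a degenerate global minimiser: zero weights map
  every input to the exact centre and the loss to zero, and training
  readily collapses there.  `train_detector(center = "init-mean")` applies
  the standard deep one-class remedy — the hypersphere centre is fixed at
  the mean feature vector of the training data under the freshly
  initialised network — which removes the trivial solution.  Even so,
  benign-only training yields only a weak mean-score ordering on small
  phantom lesions (a lesion covering a few grid cells barely moves a
  mean-pooled score without the anomalous loss branch); labelled anomalies
  remain the practically important training mode, as the screening studies
  show.
* **Optimisation.**  SGD with momentum 0.9, weight decay $10^{-4}$, batch
  32, learning rate $10^{-2}$ with cosine decay, 50 epochs by default.
  Momentum and clipping interact: disabling the clip destabilised training
  in our experiments, and substantially larger learning rates with small
  batches occasionally produced models whose scores invert on held-out
  patients; the defaults sit inside the stable region.
* **Input normalization.**  Per-image z-score standardization is applied
  by default (and recorded on the detector, so inference matches
  training): raw MIP intensities in $[0,1]$ concentrate near zero, which
  leaves SGD in the flat small-gradient regime of the pseudo-Huber map.
* **Batch normalization** is implemented but off by default: on phantoms
  it speeds up the BCE comparator yet consistently degrades FCDD — BN
  re-centres benign features away from the hypersphere centre, and the
  train/inference statistics mismatch perturbs the anomaly-score scale.
* **Subtraction MIPs.**  Negative post-minus-pre differences are clipped
  to zero before projection (subtraction MIPs visualise enhancement;
  negatives are noise or motion).  The projection uses the full volume; a
  cropped-slab variant would be a trivial extension.  The bilateral
  midline defaults to $W/2$ (phantoms are centred by construction) and is
  overridable per image.  Intensity normalization clips at the
  (0, 0.995) quantiles — robust to hot pixels without flattening lesions —
  and resampling is align-corners bilinear, so corner pixels are exact and
  a split-mirror-join round trip is lossless.
* **Degenerate inputs.**  Constant images normalize to all zeros; a
  constant heat map normalizes to zeros; single-class masks return `NA`
  pixelwise AUC and are excluded (never silently averaged); all-equal
  scores give the degenerate Youden point (all-negative by the tie rule);
  bootstrap resamples with one class are redrawn, and the CI aborts if
  more than half the draws are degenerate.
* **Seed discipline.**  A single global seed fans out to every stage
  through a counter-based integer hash (`seed_stream`), so (fold, seed)
  cells are exactly paired across models — the validity of the Wilcoxon
  pairing depends on this — and any run is reproducible from
  (configuration, seed) alone.

## Problem sizes used in the shipped experiments

The test suite and the acceptance script exercise the full pipeline at
desk scale, chosen so a complete run finishes on one CPU core: a
200-patient cohort rendered at 64x64 px for the balanced study (the
backbone sized to the image keeps the same stride and receptive field;
slimmed 8/16/32/64 channel stack, 80 epochs at learning rate 0.02), a
200-patient cohort at 32x32 px for the imbalanced operating-point
comparison (one fixed patient-grouped split, FCDD and BCE each retrained
under eight seeds, 50 epochs at learning rate 0.03), and 200-replicate
random-score simulations for the chance baselines.  The learning rates
sit deliberately below the instability threshold discussed above; the
full-width 128x128 defaults remain the package defaults for users with
more compute.

## Known limitations

* The phantom ceiling for nonmass enhancement is intrinsically lower than
  for masses (diffuse, low contrast against BPE texture) — the stratified
  explainability and detection reports show this, mirroring the clinical
  difficulty of NME.
* Detection at high BPE remains the hardest condition; the marked-BPE
  stratum can approach chance at desk-scale training budgets.
* Only 2-D MIPs are modelled; extending the loss to 3-D volumes or
  clinical covariates is out of scope.
* The backbone is intentionally small; transfer learning and pretrained
  weights are out of scope.
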