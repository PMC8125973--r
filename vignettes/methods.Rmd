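---
title: "Phasic pain recognition from facial video: models, synthetic data and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phasic pain recognition from facial video: models, synthetic data and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(painface)
```

## The problem

Phasic experimental pain — a few seconds of calibrated heat or electrical
stimulation — may or may not show up in the face. The task addressed here
is to classify a 7-second frontal face video into one of seven classes:
baseline (`B`), or heat/electrical stimulation (`H`/`E`) at intensity 1–3.
Two properties make this hard and shape every design decision in this
package. First, stimulus intensity is calibrated per person, so the same
label corresponds to very different facial displays across subjects; models
must be evaluated on subjects they never saw. Second, a substantial share
of pain samples contains *no* facial reaction at all — label noise that no
facial-expression model can overcome, only manage.

## Feature pipeline

**Facial activity descriptor.** The pipeline consumes OpenFace's 17
continuous AU intensity outputs (AU1, 2, 4, 5, 6, 7, 9, 10, 12, 14, 15, 17,
20, 23, 25, 26, 45), fixed in this canonical order so feature indices are
stable. Each series is smoothed by a centered moving average (default
window 5 frames, odd by construction, edge-replicated), then differenced
twice; forward differences are scaled by the frame rate so derivative
features read as units per second. Sixteen statistics are computed at each
level (series, first, second derivative): mean, median, standard deviation,
minimum, maximum, range, interquartile range, 10th and 90th percentile,
relative time of maximum and of minimum (first occurrence, `argmax/(T-1)`),
root mean square, mean absolute deviation, normalised trapezoidal area,
least-squares slope, and the count of strict local maxima. The original
descriptor's literature fixes the total at 48 per series but does not
enumerate the full set; the 16-statistic-per-level set above is this
package's frozen, documented choice — it spans location, scale, shape and
timing, includes all the named examples, and makes 3 × 16 = 48 exactly. Any
replacement set must keep length 48. Smoothing is applied once, before
differentiation, matching the single smoothing stage of the descriptor
pipeline.

**Spatio-temporal image.** Three frames are taken at seconds 1, 3 and 4 —
the stimulus plateau begins at second 1 and facial activity follows about
two seconds later, so these bracket onset and peak. The within-second rule
is the midpoint frame, index `floor((s + 0.5) * fps)`; it is robust to
off-by-one at second boundaries (the first-frame alternative is a
configuration choice away via the `seconds` argument granularity).
Grayscale conversion uses Rec. 601 luma weights and resizing is bilinear
(delegated to EBImage); both are unstated upstream and chosen as the
field's defaults. The encoding is idempotent on already-sized grayscale
triples because resizing is skipped when dimensions already match.

**Prediction image.** The forest's hard 7-class prediction `k` becomes a
constant 28 × 28 image of value `k/6`, exactly invertible by rounding. A
hard label (not a score vector) is encoded because the upstream description
is "numbers 0 to 6"; the encoding is isolated in one function pair so a
probability-tile variant can be swapped in without touching the networks.

## Models

Four families share one train/predict contract (per-class probability rows
summing to 1; hard label = argmax with lowest-index tie-break):

* `rfc_bl` — probability random forest on the 27,648 flattened
  spatio-temporal pixels (the automatic baseline);
* `rfc_fad` — the same forest on the 816-dim descriptor;
* `cnns_fusion` — two simple CNN branches (face image, prediction image),
  each Conv16-Conv16-Pool-Conv32-Conv32-Pool-Conv64-Conv64-GAP-Dense1024
  with ReLU throughout (3 × 3 kernels, stride-1 same padding; pools are
  3 × 3 stride 2), fused by dense layers of 1024, 512 and 128 units;
* `mnv2_fusion` — a reduced MobileNetV2 image branch (stem plus the first
  5 inverted residual blocks, ReLU6) in place of the first simple CNN.

Reading the architecture literally, each branch keeps its own Dense1024
before the fusion stack; the alternative (dropping the branch dense layer)
is noted but not taken. Input images must keep every pooled spatial
dimension at least 2 pixels, which admits 16 × 16 test-scale inputs and
rejects 8 × 8. Pretrained ImageNet backbone weights are an injection hook
(`weights` argument); random initialisation is the tested default since no
weight file ships with the package.

Forests are delegated to `ranger` (seeded, single-threaded, probability
mode). The conv-net engine is package-local: im2col convolution, depthwise
convolution and max-pooling kernels in C++ (RcppArmadillo), dense/softmax
algebra and Adam in R. Its gradients are verified against central finite
differences in the test suite. The study training schedule is 150 epochs at
learning rate 1e-4; the optimizer (Adam) and batch size (64) are unstated
upstream and fixed here. Multi-task variants add a 3-way modality softmax
head and an intensity head (4-way softmax, linear + squared error, or
sigmoid + cross-entropy); the two losses are summed with equal weights.
Scalar intensity predictions are rounded and clamped to 0–3 before the
(modality, intensity) pair maps back to a 7-class code, with `B` if and
only if intensity 0.

## Sample weighting

After training on a fold's training data, every training sample is scored
by the model's softmax probability *for its ground-truth class*; samples
scoring above 0.3 are duplicated exactly once and the model is retrained on
the enlarged set. The true-class reading (rather than top-1 probability) is
the default because the method's purpose is upweighting samples whose pain
reaction is learnable, not samples the model is confidently wrong about;
`score = "max_prob"` implements the alternative. Scores are always computed
by a model fit within the fold's training data — never with test data —
and test sets are never modified; an integrity guard asserts this on every
run. Thresholds 0 and 1 degenerate to full duplication and a no-op.

## Evaluation

Cross-validation is stratified and subject-disjoint: whole subjects are
greedily assigned (largest first, seeded order) to the fold that minimises
squared class-proportion deviation with a mild size-balance penalty. The
headline accuracy is pooled over concatenated fold predictions; the mean of
per-fold accuracies is reported alongside, since the two are not
interchangeable with unequal folds. The trivial reference model predicts
the training folds' majority class (on a balanced task its pooled accuracy
is exactly 1/k, matching the guessing level reported for near-balanced
data). The observer subset draws `round(0.1 * n)` samples per class,
allocated across subjects by largest remainder — independent per-cell
rounding would collapse to zero for small cells, whereas this reproduces
the intended per-subject, per-class draw. Predictor comparison pairs
per-subject accuracies (subjects are the exchangeable unit under
subject-disjoint folds; the pairing unit is not stated upstream) in a
two-sided paired t-test, with a per-sample McNemar test as a secondary
check; identical predictors return p = 1 by convention.

A fold may lack a class after task filtering with very small cohorts; this
is tolerated with a warning rather than re-randomised, to keep fold plans
deterministic.

## The synthetic generator

The generator emulates the statistical structure the phasic experiment
assumes, with defaults fixed once:

* 7-s samples at 25 fps (the camera rate is not stated upstream; 25 fps is
  a typical RGB rate and configurable);
* subject expressiveness ~ Gamma(shape 4, mean 1), with 8% of subjects
  fixed at 0 (people who show nothing even under strong stimulation);
* per-intensity response probability, monotone in intensity, drawn on the
  logit scale around population means (0.45, 0.65, 0.80) with SD 0.8 —
  under strong stimulation roughly one pain sample in five still shows no
  response, rising towards half at low intensity;
* baseline AU activity: smoothed Gaussian noise around a resting level,
  clipped at 0 (AU intensities are non-negative);
* responses are gamma-shaped bumps on the pain-related AUs (brow lowerer 4,
  cheek raiser 6, lid tightener 7, nose wrinkler 9, upper-lip raiser 10,
  closure channel 45), amplitude proportional to intensity ×
  expressiveness (0.7 AU units per intensity step), onset ~3 s after
  stimulus start for heat (plateau at 1 s plus ~2 s facial latency) and
  ~1 s for electrical, with a faster rise (peak 0.6 s vs 1.6 s) and much
  tighter onset timing (jitter SD 0.15 s vs 1.0 s) and magnitude
  (log-normal SD 0.15 vs 0.5): electrical nociception is near-immediate
  and stereotyped, while thermal latency and magnitude vary with the ramp
  and individual threshold. Stronger electrical stimuli additionally
  respond earlier and rise faster (0.3 s onset advance and 0.15 s rise
  shortening per intensity step), so electrical intensity carries a timing
  cue that is invariant to subject expressiveness, whereas heat timing is
  locked to the thermal ramp and heat intensity must be read from
  amplitude alone. Together these make electrical classes the more
  recognisable ones by construction — the asymmetry the evaluation
  invariants assert;
* the face renderer is schematic and deterministic: brows, eye aperture,
  nasolabial lines and mouth deform parametrically with the AU values. It
  is a stand-in sufficient to test that the image branch extracts class
  signal; it has none of the identity variation, head pose, illumination or
  registration error of real video, so passing tests demonstrate pipeline
  correctness, not clinical performance.

Every generator is a pure function of its seed and configuration; datasets
regenerate byte-identically.

## Numerical choices and test-scale parameters

Derivatives use forward differences; quantiles use the standard
interpolation (type 7); single-frame series define time-position statistics
as 0. The CNN engine initialises weights with He scaling and zero biases;
softmax losses clamp probabilities at 1e-12. The test and demonstration
configurations scale the study settings down to laptop sizes chosen once:
forests of 150–500 trees instead of 5000, 6–70 synthetic subjects instead
of 127, 1–4 repetitions instead of 30, 16–32 px network inputs instead of
96, and 10 epochs at learning rate 1e-3 instead of 150 at 1e-4 (at 10
epochs the study's rate has not moved off initialisation; 1e-3 trains the
scaled networks to above-chance accuracy while keeping the architecture
fixed). The weighting simulation uses a constant 0.6 response probability,
i.e. 40% of pain samples with no facial signal — the noise regime the
weighting method targets — over 5 generator seeds with 10 subjects,
2 repetitions per class and 3-fold subject-disjoint cross-validation.

## Known limitations

Absolute accuracies on the restricted clinical database are out of reach by
design; the package validates structure, invariants and qualitative
directions (weighting helps under response noise; electrical ≥ heat). The
schematic renderer makes the image task easier than real video. OpenFace
itself (detection, landmarks, AU regression) is upstream and out of scope —
the package consumes its CSV dialect. Multi-task training at test scale is
only checked for above-chance behaviour of both heads, not for any claim
that it beats single-task models.
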