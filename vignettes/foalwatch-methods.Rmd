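---
title: "Methods: desk-scale mare parturition detection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: desk-scale mare parturition detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Foaling is hard to catch: it happens at unpredictable hours, often at
night, and a missed dystocia can turn fatal within minutes. A fixed stable
camera sees the event clearly — the appearance of the pale fetal sac at
the mare's rear marks the delivery stage (the "MP" class, versus "MNP" for
any other frame) — but that sac is a small, low-contrast feature on a
large animal, and stables hold one to four mares in day-colour or
night-grayscale footage. `foalwatch` implements the full computational
chain for this problem at desk scale: data curation, the neural operators
of a two-stage detector specialised for small-feature detection,
COCO-style evaluation, and the per-second sliding-window decision layer
that turns frame labels into an alert.

Everything is sized to run on one CPU core in minutes. The package does
not ship or require farm footage; a synthetic scene generator provides
geometrically faithful stand-ins so that every stage is testable
end-to-end.

## Synthetic scenes and streams

`generate_scene()` renders a stable pen as a textured background with each
mare a filled ellipse: standing bodies use a length-to-height ratio of
1.5, laterally recumbent ones 2.6, so the two postures produce distinctly
shaped tight boxes. A parturition mare carries a bright elliptical blob at
the rear of the body whose radius is 10–15% of the body length — the
deliberate small-feature regime: the sac occupies roughly 1% of the body
area, so classifying MP versus MNP requires resolving detail far below
the object scale. Night scenes are grayscale (equal channels) with
additive Gaussian sensor noise. Default scene size is 384 x 216, the
curated working resolution of the pipeline. Mares are placed one per
image quadrant with jitter, which keeps up to four bodies inside the
frame without degenerate overlap.

What the generator does *not* emulate: perspective, limbs and tails,
occlusion by pen furniture, straw, other animals, illumination gradients,
or motion blur. Tests passing on these scenes therefore demonstrate that
the *algorithms* are implemented correctly and can be fit, not that the
desk-scale model would work on real footage.

`generate_stream()` simulates the per-second frame-label sequence a
detector produces on a monitoring video: before the true onset each frame
is labelled MP with probability `1 - specificity`, from the onset on with
probability `sensitivity`. Confidences are Uniform(0.5, 1) for the emitted
label — downstream rules only use the argmax label, so the confidence law
is immaterial. All generators take explicit seeds and never touch global
RNG state.

## Data curation

The curation pipeline mirrors how stable video becomes a training set:

* **Frame striding** keeps every tenth frame (indices ≡ 0 mod 10),
  timestamps derived from the 25 fps source (0.4 s between kept frames).
* **SSIM deduplication** walks frames in temporal order and drops a frame
  iff its structural similarity to the *last retained* frame strictly
  exceeds 0.76. The sequential-greedy rule is O(n), idempotent, and
  targets exactly the redundancy between adjacent frames; a pair at the
  threshold is kept. SSIM uses a 7 x 7 Gaussian window (sigma 1.5,
  K1 = 0.01, K2 = 0.03) on luminance, averaged over the fully supported
  region; a uniform-window variant with the sample-covariance correction
  matches scikit-image's default configuration to 1e-6 and is
  cross-checked against it in the test suite.
* **Resizing** is bilinear with half-pixel centres; 1920 x 1080 frames map
  to 384 x 216 (scale 0.2 on both axes) and boxes scale by the same
  factors.
* **Splitting** shuffles with a seed and rounds half-up on the training
  side, so 5680 images give exactly 3787 train / 1893 test at 2:1.
* **Augmentation** adds exactly one transformed copy per training image:
  a black occlusion rectangle 8–14 px a side (small-object occlusion at
  the working resolution), contrast jitter with factor 1 + U(0, 1),
  brightness jitter disabled, and a light Gaussian blur with sigma in
  [0.1, 0.3]. 3787 images become 7574, and per-class annotation counts
  double exactly — the doubling is a record-level identity, so it also
  holds for datasets without pixel files.

Manual anomaly screening is inherently human; it is represented only as
the ability to subset a `coco_dataset`, not as an algorithm.

## Neural operators

Feature maps are plain H x W x C arrays; convolution is im2col + BLAS
matrix multiply. Batch normalization follows
`gamma * (x - mu) / sqrt(sigma2 + eps) + beta` with moments computed from
the map when not supplied. Residual units are bottlenecks
(1x1 – BN – ReLU – 3x3 – BN – ReLU – 1x1 – BN, plus skip, then ReLU) with
a strided 1x1 projection skip when dimensions change.

Three channel-attention gates can be attached after every residual unit
of stages 3 and 4 (the semantically rich stages; stages 1–2 are never
gated):

* **SE**: global average pooling per channel, a bottleneck MLP with
  reduction r = 16 (hidden width `max(1, C/16)`), sigmoid gate, channel
  rescale.
* **GCA**: a spatial-softmax-weighted context pool per channel, then the
  same excitation MLP. The printed form of the context pool makes the
  softmax depend on the channel itself; that form is the default, with
  the shared learned 1x1-logit variant (the classic global-context block)
  available as `variant = "shared"`.
* **CBAM**: a channel gate from a shared MLP over average- and max-pooled
  descriptors, followed by a spatial gate from a 7 x 7 convolution over
  the [channel-mean; channel-max] map.

All gates are sigmoid-valued, so outputs never exceed nonnegative inputs
elementwise, and with zeroed weights every gate is exactly
`sigmoid(0) = 0.5` — a closed-form identity the tests assert.

**CARAFE** predicts, from a 1x1-compressed (64-channel) content encoding,
a softmax-normalized 5 x 5 reassembly kernel for every output location of
a 2x upsampled grid, then reassembles the source neighbourhood under
those kernels. Because every kernel sums to one, constants are fixed
points. One numerical subtlety: at border locations a predicted kernel
can place mass on taps outside the source. Predicted kernels are
therefore restricted to their in-bounds taps and renormalized (with a
uniform-over-valid-taps fallback if a saturated softmax put all its mass
out of bounds); forced kernels passed by the caller are honoured verbatim
over the zero-padded neighbourhood, which is the convention the
closed-form checks (uniform kernel = neighbourhood mean, one-hot kernel =
nearest neighbour) assume.

**CARAFE-BFP** is the neck: lateral 1x1 projections of C2–C5 to a common
width, top-down fusion with CARAFE upsampling (outputs cropped by at most
one row/column at odd sizes), P6 by stride-2 pooling of P5. Integrate
resizes P2'–P5' to the P4 resolution (adaptive average pooling down,
nearest-neighbour up) and averages them; P6' passes through, following
the stated merge of the four levels. Refine is residual — `x + T(x)` with
T a 3 x 3 convolution by default or an embedded-Gaussian non-local block —
so zero refinement weights give the identity and the scatter step then
adds exactly the integrated mean back onto every level.

**GRoIE** pools every proposal from *all five* pyramid levels with
14 x 14 RoIAlign (bilinear, 4 samples per cell, no quantization — the
enlarged grid preserves sac-scale detail), applies a per-level 3 x 3
preprocessing convolution, fuses levels by a softmax-weighted sum
(uniform by default; one-hot weights reduce exactly to single-level
extraction), and post-processes the fused grid with a CBAM-style gate.

## The desk-scale detector and its trainer

`assemble_lmpd()` composes backbone (default stage layout [1, 1, 2, 1],
widths 16/32/64/128, CBAM in stages 3–4), CARAFE-BFP (32 channels), an
RPN with 3 scales x 3 aspect ratios of anchors on P2–P6, and the GRoIE +
softmax/box head. The full 101-layer stage layout [3, 4, 23, 3] is a
configuration away but is not the test default — identical mathematics,
intractable runtime for a test suite.

Desk-scale training (`train_tiny()`) deliberately does not backpropagate
through the deep stack. The backbone, neck and GRoIE transforms are a
*frozen, randomly initialized feature extractor*; the trainable parts are
the RPN head (a 1x1 objectness/regression head over a frozen 3 x 3 + ReLU
intermediate) and the linear classification/regression head over the
flattened 14 x 14 RoI grid. Both are trained jointly by SGD with the
reference schedule (learning rate 0.005, momentum 0.9, weight decay
1e-4), with the total loss the sum: RPN objectness cross-entropy
+ balanced-L1 anchor regression + head softmax cross-entropy +
balanced-L1 box regression over IoU-balanced RoI samples. Random-feature
heads keep every gradient closed-form and the whole optimization convex,
which is what makes a 500-iteration CPU run meaningful.

Numerical choices that matter (and why):

* **Feature calibration.** Frozen features are standardized per dimension
  (statistics estimated once from the training cache and stored with the
  detector) and rescaled to a fixed squared row norm. For a linear model
  the effective step in prediction space is `lr * ||row||^2 / (1 -
  momentum)`; calibrating the norm keeps the configured learning rate in
  the stable regime for inputs as different as a 64-channel RPN cell and
  an 6272-dimensional RoI grid.
* **Box-delta normalization.** Regression targets are divided by the
  standard deviations (0.1, 0.1, 0.2, 0.2) and predictions multiplied
  back at decode time — the usual two-stage parameterization. Without it
  the balanced-L1 gradient (constant magnitude `gamma` for residuals
  above 1) causes bounded-gradient oscillation because the update step
  exceeds the target scale.
* **Balanced L1.** `b = exp(gamma/alpha) - 1` ties the two branches so
  the loss and its gradient are continuous at |x| = 1; defaults alpha =
  0.5, gamma = 1.5.
* **IoU-balanced sampling.** Negatives are split into 3 equal-width IoU
  bins over [0, 0.3) with per-bin quotas and shortfall redistribution;
  positives are drawn uniformly. k = 1 reduces to plain sampling.
* **Alternating RoI banks.** The box head trains on a per-scene bank of
  ground-truth boxes, jittered copies, interior part-crops, random and
  whole-frame negatives. At 40% and 70% of the iteration budget the bank
  is extended with the current RPN's own proposals, so the head sees the
  proposal distribution it will face at inference — the desk-scale
  analogue of alternating two-stage training. Without the part-crop and
  proposal negatives the head happily scores body-fragment slivers as
  mares, because nothing in a jitter-only bank resembles them.

The overfit property checked in the tests — 20 synthetic scenes reach
mAP50 ≥ 90% on those same scenes within 500 iterations in at least 2 of
3 seeds — is a smoke test of the machinery, not a claim about real-world
accuracy.

## Evaluation

Matching is greedy in score order, one match per ground-truth box, ties
on IoU to the lower index. AP defaults to 11-point interpolation (the
mean over recalls 0, 0.1, …, 1 of the maximum precision at or beyond
each recall); the area form (sum of interpolated precision times recall
increments) is available as `interpolation = "all_points"`. The printed
normalization of the area form in the source material is internally
inconsistent with the 11-point rule it names, so the 11-point rule is
the default and both forms are validated against exhaustive brute-force
recomputation. mAP averages over both classes and IoU thresholds
0.50:0.05:0.95; mAP50/75/90 fix the threshold; AR averages recall over
the same grid. Classes with no ground truth anywhere are excluded from
the averages (their AP is undefined, not zero); a class with ground
truth but no detections scores zero. The per-image detection cap is 100,
the COCO convention.

## The alert layer

One label per second. `best_label_per_frame()` keeps the single
highest-confidence detection; an empty frame is MNP with confidence 0,
and exact ties break toward MP — in a safety-critical monitor the cost
of a missed foaling far exceeds a spurious alert, and the tie-break is
configurable. The windowed rule scans 60-second windows at 1 s stride
and fires at the first window whose MP count *strictly* exceeds
`theta * 60` (so theta = 0.75 needs at least 46 positive frames); the
event records the window start — the reported parturition time — and
the issue time at the window's end, the earliest instant an alert can
physically be sent. Delay is measured to the issue time: with a
noiseless stream and onset at t = 100 s, theta = 0.75 fires the window
starting at 86 s, issues at 145 s, a 45 s structural delay. Raising
theta never makes an alert earlier (monotonicity is tested), and
first-detection mode fires at the first MP frame.

Per-video accuracy is decision correctness: alert fired iff an onset is
annotated. This reading makes accuracy a single percentage over a video
collection, matching how a sliding-window monitor is summarized; delay
statistics are computed over alerted videos with annotations, and can be
negative if window evidence accumulates before the annotated instant.

## Problem sizes

The test suite and the acceptance script use 384 x 216 scenes, 20-scene
training sets, 500 training iterations, 10^4-frame streams for rate
recovery and 60-video ensembles for the alert sweep. These sizes were
chosen so the full suite completes comfortably on a single CPU while
leaving each statistical check at least three standard errors of
resolution.

## Limitations

The detector's feature extractor is random, not learned; its accuracy
ceiling on anything but near-duplicate scenes is low, and no transfer to
real footage should be inferred. The synthetic scenes lack the failure
modes that dominate real deployments (occlusion, lighting, camera angle).
The alert layer assumes exactly one label per second and a single
uninterrupted stream per video. Video decoding is delegated to an
external frame extractor; the package starts from frames.
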