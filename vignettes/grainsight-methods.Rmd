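---
title: "Detecting dense, small stored-grain insects: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting dense, small stored-grain insects: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Stored-grain pest monitoring asks a hard variant of object detection: the
objects (adult beetles such as the red and confused flour beetles, or rice
and maize weevils) occupy bounding boxes of roughly 8–48 px on a side in a
640×480 surveillance frame, they sit on a visually cluttered background of
grain kernels of about the same size and colour, and — because males release
an aggregation pheromone — they frequently pile up, with three or more
individuals at a single kernel. The two species in a sibling pair are nearly
identical; the most reliable morphological cue is the shape of the pronotum
(rounded anterior angles in the red flour beetle, sharply pointed ones in
the confused flour beetle).

grainsight implements a two-stage convolutional detector built for exactly
this regime, together with the full evaluation protocol (IoU, all-point AP,
mAP, confusion matrices, ten-fold cross-validation) and a synthetic scene
generator so that every stage can be exercised and tested end to end
without access to proprietary warehouse imagery.

## The detection model

The pipeline is the classical two-stage design with three modifications
aimed at dense small objects.

**Backbone.** A fully convolutional feature extractor. The full-size `"mcs"`
backbone has four groups of three 3×3 convolutions (12 conv layers), each
group followed by 2×2 max pooling — total stride 16, 256 output channels —
plus a *feature fusion pathway*: the group-2 feature map (stride 4), which
still carries the microstructural detail that repeated pooling destroys, is
subsampled to the stride-16 grid, expanded by a 1×1 convolution and added to
the final map. The `"tiny"` backbone (two groups, stride 4, 32 channels) has
the same shape at desk scale and is the configuration used by the test
suite: with 8–48 px objects, a stride-4 feature map retains several cells
per insect where stride 16 would leave barely one.

**Anchors and region proposals.** Anchors of area $s^2$ for scales $s$ and
aspect ratios 1:1, 1:2, 2:1 (height:width; width $= s/\sqrt r$, height
$= s\sqrt r$, preserving area exactly) are tiled at every feature-map cell,
centred at $((x+0.5)\cdot\text{stride}, (y+0.5)\cdot\text{stride})$, giving
$W' H' k$ anchors. The baseline scale set $\{8, 16, 32\}$ gives the familiar
$k = 9$; the enhanced set $\{8, 16, 24, 32, 48\}$ ($k = 15$) matches the
observed label-size range of the insects and measurably improves the match
between anchors and ground truth in dense scenes. During training, anchors
crossing the image boundary are excluded from the loss; at test time all
anchors participate and decoded boxes are clipped. An anchor is a positive
example if it attains the highest IoU for some ground truth (so every
object, however awkwardly sized, has at least one positive) or if its IoU
exceeds 0.7; it is negative below 0.3; anything else is ignored.

**Soft-NMS.** Conventional NMS deletes any box whose IoU with the running
maximum $M$ exceeds $N_t$; with aggregated insects this deletes true
neighbours. Soft suppression decays scores instead:

- linear: $s_i \leftarrow s_i (1 - \mathrm{iou}(M, b_i))$ when
  $\mathrm{iou}(M, b_i) \ge N_t$, otherwise unchanged;
- Gaussian: $s_i \leftarrow s_i \, e^{-\mathrm{iou}(M, b_i)^2 / \sigma}$
  applied to every remaining box (continuous in the overlap, so no abrupt
  rank flips at the threshold).

Boxes are pruned only when their decayed score falls below a small floor.
Defaults: $N_t = 0.3$, $\sigma = 0.5$, floor $10^{-3}$. The Gaussian decay
is implemented with a negative exponent; a positive exponent would inflate
the scores of overlapping boxes, the opposite of a penalty. The floor value
is a package choice (the procedure only requires "a minimum threshold");
results are insensitive to it across orders of magnitude because scores
near the floor cannot influence rankings that matter.

**Position-sensitive prediction.** After the RoI stage there are *no
trainable layers*. A 1×1 convolution expands the backbone features (to 512
channels at full scale, 64 at desk scale), and two 1×1 heads emit
$k^2(C{+}1)$ position-sensitive class maps and $4k^2$ class-agnostic
regression maps ($k = 3$). An RoI of size $w \times h$ is split into
$k \times k$ bins; bin $(i, j)$ spans cells
$\lfloor iw/k \rfloor \le x < \lceil (i{+}1)w/k \rceil$ (and analogously in
$y$), and for class $c$ average-pools *only* its dedicated channel
$(i, j, c)$. The $k^2$ bin responses are averaged (voting) and softmaxed
across classes; the regression maps are pooled the same way into a single
$(t_x, t_y, t_w, t_h)$ delta shared by all classes. Note that with the
floor/ceil bin edges every bin covers at least one cell for any
$w, h \ge 1$ — fractional bins overlap rather than vanish — so even an 8 px
insect, occupying 2×2 feature cells at stride 4, yields a full $k \times k$
table.

**Box parameterization.** Throughout, boxes are encoded against a reference
box as $t_x = (g_x - a_x)/a_w$, $t_y = (g_y - a_y)/a_h$,
$t_w = \log(g_w/a_w)$, $t_h = \log(g_h/a_h)$; decoding inverts this exactly
(round-trip error below $10^{-6}$ px is asserted in the tests).

## Training

Losses are the standard four: cross-entropy on RPN objectness over a sample
of up to 256 anchors (positives capped at half), smooth-L1 on the anchor
deltas of positives, cross-entropy on the RoI class vote over 128 sampled
RoIs (positives capped at a quarter, positive means IoU ≥ 0.5 with a ground
truth), and smooth-L1 on the RoI deltas of positives. Optimization is Adam
with first-moment coefficient 0.9 (the "momentum" of the recipe), learning
rate 5·10⁻⁴, weight decay 5·10⁻⁴, and a single ×0.1 learning-rate decay
late in training (at 75% of the epoch budget; the recipe specifies the
factor but not the schedule point).

Several details matter for making the two-stage detector trainable from
scratch at small scale; all were adopted after probe runs showed the
failure they cure, and none alters a stated constant of the recipe:

- *Class-balanced classification losses.* A 160×160 scene yields tens of
  positive anchors among thousands of negatives; after sampling, the
  imbalance is still near 1:10. With an unweighted cross-entropy the RPN
  stays underconfident for the foreground long past a desk-scale epoch
  budget, so both classification losses weight the foreground and
  background halves of the sample equally (the weights sum to one, so the
  closed-form values of the loss on balanced inputs are unchanged).
- *A 3×3 head expansion for the tiny backbone.* The canonical design
  expands features with a 1×1 convolution before the position-sensitive
  heads, which presumes a deep stride-16 backbone whose cells already see
  large context. At stride 4 with two conv groups, a 1×1 head cannot tell
  a box covering a whole insect from one covering a fragment; the tiny
  configuration therefore uses a 3×3 expansion kernel (mcs keeps 1×1).
- *Wide-band regression training.* Only IoU ≥ 0.5 RoIs are classification
  positives, but the regression branch trains on all RoIs with IoU ≥ 0.3
  against their best ground truth: fragment boxes must learn the expansion
  that snaps them onto the full object, otherwise the highest-scoring
  fragments can never become correct detections.
- *Minimum proposal size.* Decoded proposals (and final boxes) whose longer
  side falls below the smallest anchor scale are discarded — a box smaller
  than any anchor is a decoding artifact, and at stride 4 such boxes cover
  one or two feature cells that carry no extent information at all.
- *Iterative refinement and re-scoring.* At detection time the
  class-agnostic regression is applied iteratively (default four passes:
  pool the regression maps at the current box, decode, repeat), and the
  emitted score is obtained by pooling the class maps at the *final* box.
  Everything after the RoI stage is parameter-free, so each pass adds only
  pooling work — no new layers. One regression pass cannot carry a fragment
  proposal all the way onto a 30 px insect, but the fixed-point of repeated
  refinement can; and scoring at the final box makes the score describe
  the box that is actually emitted rather than the proposal it came from.
  On the held-out synthetic study this moved mAP@0.5 from 0.30 (one pass)
  to 0.53 (four passes) without retraining.

Two more details concern where the head's training examples come from:

- *RoI sourcing.* The proposal pool for head training is the RPN's own
  output (decode, clip, top-K by objectness, Soft-NMS, keep N = 600) plus
  the ground-truth boxes and three jittered copies of each (centre shifted
  up to ±15% of the box size, log-size jittered ±0.25). Without the
  jittered copies the head would see only perfect boxes as positives: its
  classifier then treats any imperfect box as background and its regression
  branch never observes a displacement it must undo.
- *Hard backgrounds.* Background RoIs are drawn preferentially (half of the
  background sample) from near misses with IoU ∈ [0.1, 0.5). These are the
  examples that teach the head to rank a badly aligned box below a well
  aligned one; uniformly sampled backgrounds are almost all trivially far
  from any object.

"Alternating training" of the two networks with shared convolutions is
implemented as within-epoch alternation: for every image the RPN branch is
updated first (backbone included), then a fresh forward pass updates the
head branch (backbone again included). This keeps both branches training in
every epoch, which at desk scale converges faster than block-wise
alternation of whole epochs; the cycle count of the original recipe is
unspecified, and with per-image alternation the number of cycles equals the
number of epochs.

On-the-fly augmentation draws uniformly from {identity, +90° rotation,
−90° rotation, horizontal flip, vertical flip} per image per epoch — the
four label-preserving transforms; boxes transform with the pixels exactly
(the test suite checks the transformed box against the tight bounds of the
transformed pixel mask).

## The synthetic scenes

The generator emulates the *statistics* of stored-grain imagery, not its
photometry. A scene is a field of overlapping grain-coloured superellipse
kernels under a linear illumination ramp and pixel noise; insects are dark
two-ellipse composites (elytra body plus pronotum) at random orientation.
The two default classes differ in a deterministic hue shift and in pronotum
corner sharpness (superellipse exponent 2 versus 4), mirroring the rounded
versus pointed anterior angles that distinguish the real sibling species —
so the classes are separable in principle, by construction. Annotation
boxes are the tight bounds of the rendered insect mask; a draw whose box
violates the configured size or aspect range, or crosses the image border,
is rejected and redrawn (bounded retries, then an error naming the
constraint).

Configured ranges follow the source statistics: lab-like scenes are 640×480
with 1–7 insects; field-like tiles carry 20–50; body sizes span 8–48 px
(the union of the two reported label-size ranges, 8²–42² and 16²–48²);
label aspect ratios fall in [0.3, 2.2]. With probability `cluster_prob` a
placement spawns an aggregation of 3–5 individuals within about half a body
length, which produces ground-truth pairs with IoU above 0.3 — the regime
Soft-NMS exists for. Determinism is strict: a scene is a pure function of
(config, seed), and dataset generation derives per-image seeds from a
master seed by the fixed map `(master + index * 9973) mod (2^31 - 1)`.

What the generator does *not* model — motion blur, specular highlights,
partial burial in the grain mass, true beetle texture — bounds what a
passing test can claim: green end-to-end tests show the geometry, score
plumbing, optimization and evaluation work; they are not evidence about
detection accuracy on real warehouse imagery.

## Evaluation protocol

Detections are pooled across the test set per class, ranked by descending
score (ties by image id, then input order), and matched greedily within
their image: a detection claims the highest-IoU unmatched ground truth at
or above the threshold (default 0.5; 0.75 and 0.95 are also reported by the
CLI). A second detection on an already-claimed object is a false positive;
a detection whose only match is DIFFICULT-flagged is neither counted nor
penalized, and difficult objects never enter recall denominators — the
convention the annotation format is built around. AP is the area under the
precision envelope over recall ∈ [0, 1] (all-point interpolation, not the
older 11-point variant, since the definition being implemented is simply
"area beneath the precision–recall curve"); mAP averages over classes
present in the ground truth. The confusion matrix localizes first
(class-agnostic greedy matching), then compares labels on the matched
pairs; unmatched boxes are reported separately rather than folded into the
percentages, since the source protocol leaves their treatment unstated.

Ten-fold cross-validation shuffles once under a seed, splits into folds of
near-equal size (difference at most 1), trains on nine folds, evaluates on
the tenth, and reports mean ± sample (n−1) standard deviation.

## Problem sizes used by the tests

The test suite trains the `"tiny"` backbone on synthetic 160×160 scenes
with 3–8 insects of 10–30 px from two classes — 100 training and 30
held-out scenes, anchors {8, 16, 24} at stride 4 — for 16 epochs, and on
96×96 scenes for the unit-level training checks. These sizes were chosen so
that a single CPU core trains the model in minutes while the task still
exercises every component (dense anchors, clustered objects, Soft-NMS,
position-sensitive pooling). The full `"mcs"` backbone is provided and
tested for shape and gradient correctness, but the package makes no claim
that desk-scale training reproduces full-scale accuracy numbers.

## Numerical and design notes

- Coordinates are 0-based, half-open internally; the VOC/labelImg dialect
  on disk is 1-based inclusive (read subtracts 1 from xmin/ymin; write adds
  it back). Round-trips are exact.
- Tiling of oversized frames lays a grid from the top-left and shifts the
  final row/column inward (1280×720 → four 640×480 tiles with origins
  (0,0), (640,0), (0,240), (640,240)); a clipped annotation survives in a
  tile only if it keeps ≥ 50% of its area, mirroring the 50%-occlusion rule
  used for DIFFICULT labeling.
- Ties are deterministic everywhere: equal suppression scores select the
  lowest input index; equal anchor–gt IoUs resolve to the lowest anchor
  index, then the lowest ground-truth index.
- Degenerate boxes after clipping are flagged, not silently dropped, except
  in proposal selection where they cannot become RoIs.
- Feature-map RoIs are the floor/ceil cover of the image-space box in
  feature cells, never thinner than one cell.
- The per-image-seed hash keeps every derived seed inside 32-bit integer
  range.

## Known limitations

- The backbone is trained from scratch; transfer learning from pretrained
  classification networks is out of scope, so absolute accuracy on real
  imagery is not comparable to fine-tuned full-scale systems.
- The generator's class cue (hue + pronotum sharpness) is cleaner than real
  inter-species differences; confusion-matrix results on synthetic data
  overstate separability.
- Training is single-image (no batching across images) and CPU-bound;
  the design trades throughput for exactness and testability.
- With more than two synthetic classes the appearance model reuses the two
  base phenotypes, so classes beyond the second pair are not guaranteed
  separable.
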