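---
title: "Detecting small obturation voids: models, losses, and design choices"
author: "rootvoid"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting small obturation voids: models, losses, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rootvoid)
```

## The problem

After root-canal treatment, the cleaned canal space is filled (obturated)
with radiopaque material.  Gaps in that filling — *voids* — predict
treatment failure and must be found on periapical radiographs, where they
appear as small dark inclusions (a few to ~30 px at typical working
resolution) inside a bright, tapering canal band.  Small size, low
contrast, and textured bone background make this a canonical
small-object-detection problem.

`rootvoid` implements a compact single-stage detector built around three
components aimed at that regime — a residual convolution block, a
tokenized self-attention block, and a combined IoU-family box loss — plus
everything needed to exercise them end to end on a fully synthetic
phantom: data generation, training by hand-written backpropagation on the
CPU, and from-scratch mAP evaluation.

## The residual convolution block

A stride-2 3x3 convolution `y = Conv(x)` is followed by a 3x3 depthwise
convolution, and the block output is

```
out = SiLU(BN(y + DWConv(y)))
```

The skip carries the standard-convolution output *past* the depthwise
stage.  This wiring is simultaneously serial (the depthwise stage composes
with the convolution) and parallel (the addition), and it needs no
projection to stay shape-compatible at stride 2, because the skip starts
after the striding.  The intent is feature preservation: a depthwise stage
refines per-channel spatial detail, while the skip guarantees the
cross-channel features of the standard convolution — including the faint
edges of small objects — survive unchanged when the depthwise branch has
nothing to add.  With the depthwise kernels at zero and normalization
disabled the block *is* the plain convolution, which the test suite
asserts against a direct convolution oracle.

## The tokenized attention block

Global self-attention over an `H x W` map costs `O((HW)^2)` and lets
distant background dominate the attention of a 10-px void.  The tokenized
block restricts attention to local windows:

1. a linear embedding (`C -> C`) and a layer normalization over channels;
2. the map is cut into `S x S` non-overlapping tokens of `(H/S, W/S)`
   pixels;
3. scaled dot-product attention `softmax(Q K' / sqrt(C)) V` runs
   *within each token independently* (single head by default; the head
   count is a configuration knob);
4. tokens are reassembled and passed through an output linear map;
5. a residual skip adds the input.

Two choices deserve a note.  First, the attention scale: descriptions of
this family of blocks vary between dividing by the channel count `C` and
by `sqrt(C)`; we use `sqrt(C)`, the dot-product-attention convention, so
that logit variance is independent of `C`.  Second, the outer residual
skip plus a zero-initialized output projection mean a freshly built block
is exactly the identity: attention fades in during training rather than
destroying the signal at initialization.  Cross-token isolation (nothing
crosses a token boundary) is asserted by perturbation tests.

Tokens per side default to `S = 4`; the input resolution must make the
stride-8 grid divisible by `S` (640 -> 80 -> 20-px tokens; 160 -> 20 ->
5-px tokens).

The fused block (`c2fcs_forward`) appends this attention stage to a
CSP-style split-transform-concat fusion block (1x1 expansion, a compact
inverted bottleneck on half the channels, concatenation, 1x1 fusion); it
sits immediately before the highest-resolution detection head, where small
objects live.

## The box regression loss

For a predicted box `p` and ground truth `g` in an `H x W` image frame,
with `IoU` the intersection-over-union, `rho^2` the squared center
distance, `c^2` the squared diagonal of the smallest enclosing box,
`d1^2, d2^2` the squared distances between the top-left and bottom-right
corner pairs, and

```
v     = (4 / pi^2) (arctan(w_g / h_g) - arctan(w / h))^2
alpha = v / ((1 - IoU) + v)
```

the package provides:

* `ciou_loss`:  `1 - IoU + rho^2 / c^2 + alpha v`  (complete IoU);
* `mpdiou`:     `IoU - (d1^2 + d2^2) / (H^2 + W^2)` — note this is a
  *similarity* (1 for identical boxes, possibly negative), implemented
  verbatim in that orientation; it is reported, never trained on;
* `cmiou_loss`: `1 - IoU + (d1^2 + d2^2)/(H^2 + W^2) + rho^2/c^2 + alpha v`,
  the combined objective actually used for training.

The point of the corner-distance term is gradient coverage: when boxes are
disjoint, `1 - IoU` is flat and provides no learning signal, while the
corner and center penalties keep pulling the prediction toward the target.
The test suite verifies this by central differences on random disjoint
pairs.

Numerical conventions: the corner normalizer uses the *image* frame
(default 640 x 640 = training resolution), not the enclosing box; `alpha`
is treated as a constant during backpropagation (the stop-gradient
convention of the CIoU literature; `box_loss_grad(exact_alpha = TRUE)`
gives the exact derivative for finite-difference checks); widths and
heights inside the arctan ratio are clamped to `>= 1e-7` px so degenerate
predictions stay finite and differentiable, with the clamp zeroing the
corresponding gradient component.  Areas are `(x2 - x1)(y2 - y1)` on
continuous coordinates, so the half-open/closed pixel question does not
arise.  A caveat the tests encode: the penalty `alpha v` is symmetric
under exchanging the two boxes (both `v` and `IoU` are); the asymmetry of
the roles lies in validation (the ground truth must be non-degenerate) and
in the gradient treatment, not in the value.

## The detector

The nano-scale reference model is fully convolutional:

* **backbone** — five residual convolution blocks, each stride 2, with
  channels (8, 16, 24, 32, 48) at width multiplier 0.5, giving feature
  maps at strides 8, 16, 32;
* **neck** — FPN top-down fusion (1x1 laterals, nearest 2x upsampling,
  3x3 merge) followed by PAN bottom-up fusion (stride-2 3x3 downsampling,
  3x3 merge);
* **heads** — one 1x1 convolution per scale producing 4 box offsets, an
  objectness logit, and one class logit per class; the fused
  attention block sits on the stride-8 path right before its head.  A
  single one-to-many head per scale with NMS at inference is used
  throughout.

Decoding is anchor-free.  Cell `(r, c)` at stride `s` predicts

```
cx = (c - 1 + 2 sigmoid(tx) - 0.5) * s      w = exp(tw) * s
cy = (r - 1 + 2 sigmoid(ty) - 0.5) * s      h = exp(th) * s
```

The `2 sigmoid - 0.5` offset ranges over (-0.5, 1.5) cells so neighbour
cells can also represent the center; `tw` is clamped at 8 before the
exponential.  The score is `sigmoid(obj) * max(sigmoid(cls))`.

**Assignment.**  Each ground-truth box goes to one scale by area
(`<= 32^2` px to stride 8, `<= 96^2` to stride 16, else stride 32) and to
three cells there: the containing cell plus the nearest neighbour in x and
in y.  A cell serves at most one ground truth (first wins, insertion
order).

**Loss.**  `total = 0.5 cls + 5 box + 1 obj` via `compose_total_loss`:

* *box* — mean CMIoU (or CIoU, per configuration) over assigned cells,
  differentiated analytically through the decode transform;
* *cls* — binary cross-entropy on the class logits at assigned cells;
* *obj* — binary cross-entropy on all cells, with two standard devices
  that proved necessary for learning at desk scale: the positive target is
  the IoU of the currently decoded box with its ground truth (detached),
  so scores track localization quality and duplicate neighbours fade; and
  negatives carry a detached focal factor `p^2` with the whole term
  normalized by the positive count, so a confident false positive on
  background receives a strong corrective gradient instead of being
  averaged away over thousands of cells.

The distribution-focal localization term that appears alongside
classification and box terms in some detector formulations is not defined
in our setting and is omitted; the composite keeps a generic third slot.

## Training

No deep-learning framework is involved: forward and backward passes of
every layer (im2col convolution, depthwise convolution, batch
normalization, SiLU, layer normalization, attention) are implemented
directly, the convolutions in C++, and verified against central
differences.  The optimizer is AdamW with the study's settings as
defaults: learning rate 0.01, batch 16, `beta1 = 0.937` (the quoted
"momentum parameter" mapped to AdamW's first moment; `beta2 = 0.999`),
weight decay 5e-4.  Batch normalization uses batch statistics in training
and running estimates (momentum 0.1) at evaluation.

Two stabilizers are on by default in the loop itself: a linear learning
rate warmup over the first 3 epochs and global gradient-norm clipping at
10.  Without them, roughly one in three random initializations of the
desk-scale run stalls in a high-loss region during the first epochs.  A
cosine decay schedule is available behind `lr_schedule = "cosine"`; early
stopping is deliberately absent so runs are deterministic.  All
randomness (initialization, shuffling, mosaic) flows from one seed, and
two runs with equal seed and data are bit-identical.

**Desk-scale defaults.**  The demonstration runs train the nano model at
160 x 160.  At this scale the study-scale learning rate of 0.01 diverges
under AdamW, so the demos (`demo_run`) use 0.003 with the cosine schedule;
this is a package choice, documented here, not a reproduction of any
published schedule.  The demonstration problem sizes — one image for the
overfit check (200 epochs), 64 training plus 16 validation images for the
learning demo (50 epochs) — are the package's chosen benchmark sizes.

## Ablation switches

The three ingredients can be toggled independently for ablation studies:
`detector_config(use_resconv = FALSE)` replaces the backbone blocks with
plain conv + BN + SiLU blocks, `use_tokatt = FALSE` leaves the stride-8
fusion block without its attention stage, and `train_config(loss = "ciou")`
swaps the box objective.  `scripts/ablation.R` runs the full 2^3 grid on
the desk-scale demo and writes a CSV of validation metrics (expect about
25 minutes at the default 50 epochs on one CPU core).

## Evaluation

Matching is greedy in descending score order (ties by insertion order):
a prediction matches the unmatched same-class ground truth of highest IoU
if that IoU reaches the threshold; each ground truth matches once.
Precision and recall accumulate per prediction; AP is the 101-point
interpolated area (precision envelope made non-increasing, sampled at
recall 0.00–1.00 in steps of 0.01) — the community convention behind
"mAP50-95", chosen because the bare integral definition leaves the
interpolation unspecified.  mAP50 averages per-class AP at IoU 0.5;
mAP50-95 over thresholds 0.50:0.05:0.95 and then classes.  The scalar
precision/recall pair is reported at the confidence threshold maximizing
F1 at IoU 0.5, since no operating point is otherwise defined.  For curve
construction the decoder runs at a low confidence floor (0.05).  Every
component is cross-checked in the tests against an independently coded
brute-force reference.

## The phantom generator

The synthetic module emulates *appearance statistics*, not anatomy: a dark
tissue background with low-frequency texture; one to three bright,
curved, downward-tapering canal bands (sine-perturbed centerline, soft
1.5-px edges); zero to four darker soft-edged elliptical voids placed
fully inside a canal with non-overlapping boxes; Gaussian blur and
additive Gaussian noise applied last.  Defaults (640 x 640, canal widths
18–44 px, void diameters 4–28 px, canal contrast 0.35–0.55, void
contrast 0.25–0.45, blur sigma 0.6–1.5, noise sd 0.03) put the voids in
the few-to-30-px regime at working resolution.  The default study is 612
training and 156 validation images — the split sizes are explicit fields
rather than derived from a fraction, because 612/768 is not exactly 80%;
when a user supplies a total count instead, validation takes
`floor(0.2 n)`.

Void boxes are recorded *before* blur; at the default sigmas blur moves
apparent edges by under 2 px, which we accept as label noise mirroring
clinical annotation uncertainty.  The `phantom_spec_easy()` regime
(160 px, 1–2 voids of 8–20 px, contrast ~0.45, noise 0.01) defines the
high-contrast, low-noise conditions for the learning demonstrations.

What passing tests on phantoms does **not** show: robustness to real
radiographic physics (scatter, beam hardening), overlapping anatomy,
multi-tooth layouts, or clinical annotation variability.  The phantom's
job is to give the detector a learnable small-object task with controlled
statistics, so that architecture, loss, and metric code can be validated
end to end.

## Degenerate inputs and edge cases

* IoU of two zero-area boxes is defined as 0; a zero-area ground truth is
  rejected by the losses.
* An empty prediction set yields an empty PR curve and AP 0; evaluation
  with no ground truth at all returns a report flagged invalid.
* Score ties everywhere break by insertion order, so results are
  deterministic.
* Mosaic drops annotations whose clipped area falls below 1 px^2;
  letterbox mappings are recorded and exactly invertible.
* A non-finite training loss aborts with the offending batch named.

## Known limitations

The nano model is a topology demonstration, not a capacity match for any
published detector; single-class use is the tested path (`nc > 1` is
plumbed but not exercised by phantoms); the attention block's head count
beyond 1 is implemented but not used by the reference configuration; and
strict shift-equivariance holds at the stride-8 backbone stage but not at
the heads, whose receptive field is global through the top-down neck.
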