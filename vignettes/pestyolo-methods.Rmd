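---
title: "Detecting light-trap insects with pestyolo: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting light-trap insects with pestyolo: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pestyolo)
```

## The problem

Light traps photograph the insects they catch from above: many small dark
bodies on a bright, reflective plate, often touching or overlapping,
surrounded by debris, scales and specular highlights. Automated monitoring
needs every insect located and classified, which is a hard detection
problem for three reasons: the objects are tiny (linear scales of a few
percent of the image), densely packed, and embedded in structured clutter
that produces false positives.

`pestyolo` implements a lightweight one-stage detector for this regime: a
CSP (cross-stage-partial) backbone in the YOLOv5-s mould whose backbone
blocks carry a *coordinate-and-local attention* (CLA) operator, a *grouped
spatial-pyramid-pooling cascade* (GSPPF) on the deepest feature map, GIoU
box regression, Gaussian Soft-NMS post-processing, and a COCO-style
AP/mAP evaluator with a noise-robustness harness. Everything — including
the convolutions and backpropagation — runs on a small tape-based autodiff
engine over base-R arrays, so the whole stack is trainable and testable on
CPU with no external framework and no external data.

## The attention operator (CLA)

Given a feature map $X \in \mathbb{R}^{C\times H\times W}$, two 1-D average
pools encode each channel along height and width:

$$z^h_c(h) = \tfrac1W \sum_i x_c(h,i), \qquad
  z^w_c(w) = \tfrac1H \sum_j x_c(j,w).$$

The two profiles are concatenated along the spatial axis and squeezed by a
shared $1{\times}1$ convolution $C \to C/r$, batch-normalized and passed
through a Leaky ReLU; the result is split back into its height and width
parts, each expanded by its own $1{\times}1$ convolution $C/r \to C$ and
gated with a sigmoid, yielding directional gates $g^h \in (0,1)^{C\times H}$
and $g^w \in (0,1)^{C\times W}$. A parallel pointwise *local-context*
branch $x^l = \delta(C_2(\delta(C_1(x))))$ (both $1{\times}1$, bottleneck
$C/r$, $\delta$ = Leaky ReLU) modulates the output:

$$x'_c(i,j) = x_c(i,j)\, g^h_c(i)\, g^w_c(j)\, x^l_c(i,j).$$

Plain coordinate attention (`ca_forward()`) omits the $x^l$ factor and is
kept as the ablation baseline. Design points that the operator's written
form leaves open, and how this package resolves them:

* **Reduction ratio `r`.** Not stated; we default to 32, the value used by
  the coordinate-attention design this operator builds on. It is
  configurable, and for narrow feature maps the model builder falls back
  to the largest divisor of $C$ that keeps the bottleneck at least one
  channel wide.
* **Leaky ReLU slope.** Not stated; default 0.1, configurable.
* **Batch normalization.** The bottleneck equation omits it but the
  operator's block diagram includes it; we include it, on the shared
  bottleneck only.
* **Boundedness of the local factor.** As written, $x^l$ is an unbounded
  multiplicative factor (Leaky ReLU output, no sigmoid). We implement it
  exactly so; a sigmoid-bounded variant is available behind
  `cla_params(..., bounded_local = TRUE)` but is off by default.
* **Gate shape.** The computation produces $C{\times}H$ and $C{\times}W$
  gates; they are broadcast over the remaining axis.

## The grouped pooling cascade (GSPPF)

SPPF fuses receptive fields on the deepest map with three cascaded
$5\times5$ stride-1 max pools: the cascade of 3 equals parallel pools of
kernel 5, 9 and 13 (a property the tests assert bitwise). GSPPF pushes the
same idea to finer channel granularity: after an entry convolution the map
is split into four equal channel groups $v_1..v_4$, and

$$y_1 = v_1,\quad y_2 = \mathrm{SPPF}_2(v_2),\quad
  y_i = \mathrm{SPPF}_i(v_i + y_{i-1}),\ i \in \{3,4\},$$

with the concatenation $[y_1,\dots,y_4]$ fused by an exit convolution. The
cascade is directional: permuting groups changes the output.

Channel bookkeeping is the one genuinely open design point. We keep GSPPF
a drop-in replacement for SPPF: the entry conv maps $C\to C$, each
internal SPPF maps $C/4 \to C/4$ with hidden width $C/8$, and the exit
conv maps $C \to C_{\text{out}}$. Under this budget the grouped cascade is
roughly parameter-neutral against SPPF (it redistributes rather than
inflates the pooling stage), which is the main source of uncertainty in
the architecture profile: the assembled full model counts 7.14 M
parameters against the published 7.35 M for the same configuration, a 3%
gap attributable to `r` and to these widths; the CLA/GSPPF-free baseline
matches its published 7.08 M / 16.0 GFLOPs profile to printed precision.

## Detector assembly, decoding, loss

The network is the small CSP detector: a 6×6 stride-2 convolution stem,
four backbone stages (each a CSP block, optionally followed by CLA),
SPPF or GSPPF, an FPN+PAN neck, and three anchored $1\times1$ prediction
heads at strides 8/16/32 with three anchors each. Raw cell predictions
$(t_x,t_y,t_w,t_h,o,c_1..c_K)$ decode as

$$\text{center} = (2\sigma(t_{xy}) - 0.5 + \text{cell})\cdot\text{stride},
\qquad \text{size} = (2\sigma(t_{wh}))^2 \cdot \text{anchor},$$

with score $\sigma(o)\cdot\max_k \sigma(c_k)$. The decode parameterization
is the one standard in this detector family (the source description of the
head is schematic); it bounds center offsets to $(-0.5, 1.5)$ cells and
sizes to $(0,4)$ anchors.

Training minimizes three terms: mean $(1-\mathrm{GIoU})$ over assigned
cells (per scale, summed over scales), binary cross-entropy of the
objectness logit against an IoU-valued target (the decoded box's IoU with
its ground truth, detached — the train-time confidence semantics), and
binary cross-entropy over class logits, weighted 0.05 / 1.0 / 0.5 with
per-scale objectness balance (4.0, 1.0, 0.4). Labels are assigned to every
anchor within a 4× width/height ratio and to the home cell plus its two
nearest neighbours (cross-grid assignment). All of these are the
conventions of the detector lineage the model extends; the loss-balance
weights are configurable.

Two numerical conventions deserve explicit mention because they make the
stated optimization recipe (SGD, lr 0.01, momentum 0.937, weight decay
5e-4, batch 16, cosine decay) behave at small batch sizes:

* **Loss gain.** The per-image loss is multiplied by the nominal batch
  size (16) before backpropagation, independent of how many images are
  accumulated per optimizer step — the convention under which this lr
  regime was designed. Without it, updates are an order of magnitude too
  small and optimization stalls.
* **Instance-style normalization at inference.** Training processes one
  image per step, so batch normalization reduces to per-image (instance)
  statistics, and the network learns to rely on them. The assembled model
  therefore normalizes with per-image statistics at inference as well —
  deterministic per image and exactly the regime the weights were trained
  in. Population running averages are still tracked but are not a faithful
  substitute: replacing per-image statistics by any fixed average distorts
  the learned activations and collapses detection quality. The
  operator-level array APIs (`cla_forward()`, `sppf()` and friends) keep
  the conventional stored-statistics semantics, which is what their
  nested-loop test oracles specify.

A three-epoch linear lr warmup precedes the cosine decay.

## Post-processing

Soft-NMS rescopes rather than deletes: per class, the highest-scoring
unprocessed box is fixed and every remaining box of the class is rescored

$$S_i \leftarrow S_i \exp(-\mathrm{IoU}(B_{\max}, b_i)/\alpha^2),
\qquad \alpha = 0.5,$$

iterating greedily (the original Soft-NMS algorithm; the rescoring rule
alone does not fix single-pass vs greedy, and greedy matches the cited
method). A final threshold (default 0.001, configurable) makes the output
finite; with threshold 0 the box count is preserved and only scores
change. Suppression is per class, following the source's own description
of its NMS. Classical hard NMS is available for ablation.

## Evaluation

Average precision is the area under the monotone (all-point interpolated)
precision envelope over recall, computed from greedy score-ordered
matching: a detection is a true positive iff its IoU with a still
unmatched same-class ground truth reaches the threshold, each ground truth
matching once. mAP@0.5 averages per-class AP at IoU 0.5 over classes
present in the ground truth; mAP@[0.5:0.95] additionally averages over the
ten thresholds 0.50..0.95. Classes absent from the ground truth are
excluded from the means (and logged) rather than scored zero. A 101-point
interpolation is available for cross-checking; at the scales exercised
here the two differ by less than $10^{-3}$.

The robustness harness corrupts a labelled image set with salt-&-pepper
noise (exactly `round(level*H*W)` pixels forced to pure black or white,
levels 0.005..0.05 in steps of 0.005) or additive Gaussian noise (mean
0.1, sd 0.05 on the unit intensity scale at the top level), re-runs
detection at each level and tabulates mAP against noise level; the level-0
row is exactly the plain evaluation.

## The synthetic scene generator

`generate_scene()` renders what the stack needs to be exercised: a bright
textured trap plate with an illumination falloff, dark elliptical insects
with class-specific aspect ratio, shade and optional leg strokes, plus
*unlabeled* gray clutter blobs and *unlabeled* bright reflection discs
that exist purely to provoke false positives. Labels are the exact
bounding boxes of the rendered masks. The default size distribution is
concentrated at linear relative scales 0.005–0.05 with occasional large
outliers (probability 0.05, up to 0.3), mirroring the heavy-tailed size
profile of real trap catches; a `density` parameter controls how often an
insect is deliberately placed overlapping an earlier one, reproducing the
dense-catch pathology. Everything is a deterministic function of the seed.

What the generator does *not* emulate: real insect texture, legs/antennae
at realistic resolution, motion blur, specular anisotropy, or the
inter-class confusability of real catches. Passing tests on these scenes
therefore demonstrates the correctness of the pipeline (geometry, losses,
suppression, metrics) and its trainability, not field-ready accuracy.

## Problem sizes used by the test suite

The correctness oracles run on feature maps of a few channels and a few
pixels, where nested-loop references are exact. The end-to-end gates use
deliberately small study conditions so that full training runs complete on
a single CPU: the overfit gate trains a width-0.25 / depth-0.33 model at
64×64 input on 8 scenes with 3 insects each (linear scales 0.2–0.4, 2
classes) for 150 epochs with per-image updates and augmentation disabled,
and must reach train mAP@0.5 of at least 0.9; a second gate trains 5
epochs on 50 scenes and must strictly decrease the total loss; the
robustness gate sweeps the full salt-&-pepper grid with the overfit model
and must be non-increasing up to seeded jitter. The architecture profile
(parameter count and GFLOPs) is computed at the full 640×640 / 24-class
configuration, where it is a deterministic function of the topology.

## Known limitations

* Pure-R execution: a full-size 640×640 forward pass takes seconds, so
  full-scale training is out of reach; the package targets correctness,
  profiling and small-scale experimentation.
* Batch normalization sees one image per step, so the model is effectively
  instance-normalized; inference mirrors that (see above), which differs
  from large-batch pipelines.
* Transfer-learning initialization is out of scope; training starts from
  seeded random weights, so absolute accuracies on real data are not
  comparable to pretrained pipelines.
* The GSPPF channel budget and attention reduction ratio are reasoned
  defaults, not published facts; the parameter profile carries a
  corresponding few-percent uncertainty.
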