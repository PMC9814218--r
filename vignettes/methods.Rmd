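---
title: "Methods: weakly supervised triage of prostate biopsy slides"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: weakly supervised triage of prostate biopsy slides}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The clinical problem and the labels

Prostate adenocarcinoma found on core needle biopsy ranges from indolent
disease, safely managed by active surveillance, to aggressive disease
requiring definitive therapy. The management-relevant quantity is the share
of high-grade architecture in the tumour: this package labels a whole slide
image (WSI) **aggressive** when Gleason pattern 4 and 5 regions occupy at
least 20% of the total annotated carcinoma area, **indolent** when they
occupy less, and **benign** when the slide carries no carcinoma at all
(`assign_wsi_label()`). The 20% boundary is treated as *inclusive*: the rule
is stated formally as "greater than or equal to 20%", and the formal
statement wins over looser prose renderings ("less than / more than") that
leave exactly-20% unassigned. For tile-level supervision, Gleason pattern 3
is grouped as indolent morphology and patterns 4 and 5 as aggressive
morphology (`pattern_to_class()`).

Area is measured on free-hand annotation polygons including enclosed tumour
stroma. Overlapping polygons of the same pattern group are unioned before
measuring so sloppy free-hand overlap is not double counted; polygons of
*different* groups that overlap are counted once for each group, since the
source protocol does not address mixed-pattern overlap. With no polygon
clipping library in the dependency set, union areas fall back to supersampled
rasterization (about 2 samples per pixel, capped at 4e6 cells) only when
bounding boxes actually overlap; disjoint polygons use the exact shoelace
area. The approximation error is well under 1% at that sampling density.

## Tissue detection and tiling

Slides are scanned against a near-pure white background, so tissue detection
is global Otsu thresholding on the ITU-R 601 luminance
(`0.299R + 0.587G + 0.114B`); the channel used for thresholding is not
dictated by the protocol, and standard grayscale is the natural choice for
H&E on white. A pixel is tissue when its luminance is *at or below* the
threshold. The mask is kept at a downsampled grid (default cell size 16 px, a
memory choice; tile tissue fractions are measured on this grid and documented
as an approximation). Candidate tiles come from a regular stride grid
(defaults 512-px tiles, stride 256) and are kept when at least
`min_tissue_fraction = 0.25` of the window is tissue — a config value, chosen
to drop near-empty edge tiles without discarding fragment borders; the
protocol says only that tiles come "from the tissue regions".

## The tile classifier

The trainable unit maps a tile to **two independent sigmoid probabilities**,
`p_indolent` and `p_aggressive`. Two independent heads (rather than one
3-way softmax) are forced by three observations: the training loss is binary
cross-entropy, per-label ROC curves are reported, and slides can legitimately
emit *both* labels at once (double-label outputs). Benign is the absence of
both.

The backbone is pluggable behind `tile_classifier()`; the implementation
ships a small convolutional network written in plain R: tiles are
average-pooled to a fixed 16x16x3 representation, then two 3x3 convolution
blocks (each conv -> batch normalization with affine parameters -> ReLU, with
a 2x2 average pool between them), global average pooling, and a dense
two-sigmoid head. All forward/backward arithmetic is explicit matrix algebra,
so training is bit-reproducible on one CPU and the analytic gradients are
verified against numerical differentiation in the test suite. Large
pretrained backbones and their transfer chains are deliberately out of scope:
the training *mechanics* are the subject here, not the weights.

Partial fine-tuning (`partial_finetune_setup()`, policy `"partial"`, the
default) trains only the batch-normalization affine parameters (gamma, beta)
and the final classification layer; convolution weights stay frozen at their
initialization. Policy `"all"` trains everything. The optimizer is Adam with
learning rate 0.001, beta1 0.9, beta2 0.999, batch size 32.

## Training: hard mining, warmup, and the cross-head question

Training alternates inference and optimization. Each draw samples three
training slides, one per label. During the **warmup** epochs, tiles are
sampled at random: in `FS+WS` mode, carcinoma-slide tiles come only from
positions whose centre lies inside an annotation polygon of the class
matching the slide label (benign slides always sample from all tissue); in
`WS` mode all slides sample from all tissue, with the slide label standing in
for tile truth. After warmup, **hard mining** takes over: every sampled
slide's tissue tiles are scored, and the `k = 8` highest-probability tiles
per head enter a training pool; when the pool reaches `N = 256` tiles it is
shuffled and consumed in batches of 32 (leftovers persist — tiles are never
silently dropped). Early stopping tracks a WSI-level validation loss — mean
binary cross-entropy of the max-aggregated slide scores over both heads, so
the stopping criterion lives in the same metric family as the reported
slide-level results — and halts after 10 epochs without improvement,
returning the parameters of the best epoch.

Two genuinely open design points were resolved as follows:

* **Weak labels for mined tiles (cross-head supervision).** A mined tile is
  positive for the head matching its slide's label and, by default,
  **negative** for the other head (`cross_label = "negative"`); benign-slide
  tiles are negative for both. The defining property of hard mining is that
  it finds likely false positives *on slides that are negative for a head* —
  and an indolent slide is a negative for the aggressive head. Without those
  cross-head negatives the aggressive head never sees a negative example of
  Gleason-3-like texture (it is positive on aggressive slides, absent on
  benign ones) and converges to "anything non-benign", saturating indolent
  slides' aggressive scores. The cost is asymmetric label noise: aggressive
  slides do contain pattern-3 regions, so their mined tiles supply some wrong
  negatives to the indolent head. That asymmetry — an accurate aggressive
  head, a noisier indolent head with inflated confident errors — is exactly
  the behaviour this family of models exhibits, and `cross_label = "masked"`
  is available to silence the opposite head instead.
* **Warmup length.** "A few epochs" is exposed as `warmup_epochs` (default
  2). The default suits a *pretrained* backbone whose initial scores already
  rank carcinoma above background. A cold-started tiny backbone needs the
  warmup to establish that ranking before mining begins; otherwise mining can
  lock into a degenerate equilibrium in which the truly diagnostic tiles are
  never selected (we observed the aggressive head inverting this way). The
  desk-scale runs therefore use `warmup_epochs = 15` together with
  `draws_per_epoch = 16` and `subset_size = 96`, which give the fixed 0.001
  learning rate roughly a thousand gradient steps; with 12 training slides
  the published pool size of 256 would trigger optimization too rarely for
  the patience window.

## Slide-level inference

A slide's score per head is the **maximum** tile probability
(`aggregate_wsi()`). The label set contains every head whose score reaches
the decision threshold; 0.5 is the default — the natural operating point of a
sigmoid head; the source protocol reports threshold-free AUCs and does not
state its hard-call threshold, so the value is configurable. Slides whose two
scores both pass are first-class **double-label** outputs; a legacy exclusive
label takes the larger-scoring member (exact ties break toward aggressive,
the clinically conservative direction). Heatmaps colour tile footprints with
a jet colormap; overlapping strides resolve by per-pixel maximum, consistent
with max aggregation.

## Evaluation

`evaluate_set()` binarizes truth per head (`truth == head`), scores ROC-AUC
(threshold sweep with trapezoidal integration; equal to Mann-Whitney with
ties counted one half), log loss (probabilities clipped at 1e-15), accuracy,
sensitivity and specificity, each with percentile bootstrap confidence
intervals (1000 iterations, resampling slides). Two hard-call modes exist:
`exclusive` scores the single exclusive label; `double_label_accept` accepts
a slide that carries both labels as a call of the *true* class whenever the
truth is one of the two (all other slides keep their exclusive call). Note
that the naive alternative — counting every member of the label set as a
positive call — would create new false positives on the opposite head and
could *lower* accuracy; acceptance as implemented only relaxes correctness,
so double-label accuracy structurally dominates exclusive accuracy — the
property version of the indolent metrics improving under double-label
acceptance. AUC itself is call-free and identical across modes: how the
original indolent AUC was recomputed "under acceptance" cannot be
reconstructed from calls alone, so only hard-call metrics change here and the
ambiguity is noted.

## Rater agreement

Inter-rater agreement across multiple raters uses Bennett's S generalized by
mean pairwise agreement: `Po` is the mean over items of the fraction of
agreeing rater pairs, and `S = (c Po - 1)/(c - 1)` with `c = 3` categories —
the standard multi-rater generalization, chosen because the source cites its
S reference without a formula; it reduces to the classic two-rater S and is
oracle-testable by pair enumeration. Intra-rater test-retest agreement uses
weighted kappa over ordered categories (benign < indolent < aggressive) with
linear weights by default (quadratic available); the original weighting
scheme is unrecoverable. The interpretation scale is banded
left-open/right-closed (poor at or below 0, then slight / fair / moderate /
substantial / almost perfect in 0.2 steps) so the printed scale's gaps (such
as between 0.0 and 0.01) still map every value to exactly one band.

## The synthetic slide generator

`generate_slide()` composes elongated tissue fragments (biopsy cores) on a
pure white background with three procedural textures: benign tissue (light
pink, smooth, sparse round voids), GP3-like carcinoma (mid-tone purple with a
regular small-ring motif — the well-formed-gland cue) and GP4/5-like
carcinoma (dark purple fused irregular blobs). Carcinoma is painted inside
rectangles that double as the annotation polygons, so the emitted label
follows from the same area-fraction rule the labeling module implements, and
the realized GP4/5 fraction tracks the requested one to within a few percent.
Mean luminance is ordered benign > GP3-like > GP4/5-like, and tissue
channels are clipped at 235 against a pure-white (255) background, so the
global Otsu threshold always falls in the empty luminance gap above the
tissue and detection is near-exact by construction (the suite checks at or
above 99% coverage of tissue pixels on a fine mask grid).

Slides default to 1536x1024 px with 128-px tiles in the test runs — roughly
a thousandth of a clinical gigapixel slide. `generate_dataset()` emits
balanced manifests; indolent slides draw GP4/5 carcinoma fractions from
{0, 0.06, 0.12, 0.17} and aggressive ones from {0.25, 0.45, 0.70, 1.00},
deliberately including near-boundary values so borderline/double-label
behaviour is exercised.

**What passing on synthetic slides does and does not show.** The textures
are tuned for separability, not histological realism: no staining variation,
scanner artifacts, pen ink, tissue folds, nuclear detail, or ambiguous
transitional architecture. End-to-end results on this data validate the
*pipeline mechanics* — tiling, mining dynamics, aggregation, statistics —
and say nothing about diagnostic accuracy on real H&E slides.

## Numerical choices and degenerate inputs

* Otsu threshold ties break toward the smallest threshold; single-bin
  histograms are rejected as degenerate.
* Hard-mining ties break by row-major tile position; `k` larger than the
  grid returns the whole grid.
* Batch normalization uses batch statistics in training and running
  statistics (momentum 0.9, epsilon 1e-5) at inference, so batched and
  unbatched predictions agree exactly.
* Masked (tile, head) pairs contribute zero loss and zero gradient; an
  all-masked batch is an error.
* Log-loss probabilities are clipped at 1e-15; TPR/FPR with empty
  denominators are flagged `NaN` rather than silently zeroed; single-class
  AUC is an error in `roc_auc()` and a skipped resample inside the
  bootstrap (more than half skipped is an error).
* Empty annotation lists are a valid benign slide; an empty tile grid is a
  valid result of a tile larger than the slide, but an error where scoring
  requires at least one tile.

## Problem sizes used by the checks

The end-to-end runs use 30 synthetic slides (12 train / 6 validation / 12
test), 128-px tiles at stride 128, and the training configuration above;
the label-shuffled control repeats the weakly supervised run five times on
label-permuted manifests and averages both heads' WSI AUCs over the
validation and test splits. Bootstrap coverage is measured with 200
repetitions of a binormal score model with true AUC 0.8 at n = 100 slides,
1000 bootstrap iterations each. Agreement statistics are exercised on
simulated rating matrices up to 10,000 items.

## Known limitations

* The backbone is intentionally tiny; nothing here speaks to the accuracy
  achievable with a modern pretrained encoder on clinical slides.
* Multi-resolution slide pyramids, vendor formats (SVS/JPEG2000), stain
  normalization and artifact removal are out of scope; rasters are plain
  tiled TIFF/PNG at a single resolution.
* All fragments on a slide are treated as one specimen, as the protocol
  prescribes; per-core reporting is not attempted.
* The 20% rule makes borderline compositions (GP4/5 near 20%) intrinsically
  unstable under annotation noise; the double-label mechanism surfaces, but
  does not resolve, that instability.
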