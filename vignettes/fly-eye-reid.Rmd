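---
title: "Connectome-constrained fly-eye networks and across-day re-identification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Connectome-constrained fly-eye networks and across-day re-identification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flyeye)
```

## The model

The *Drosophila* optic lobe is organised retinotopically: behind each of the
~850 ommatidia sits a repeating column of "modular" cell types (one neuron per
column) through the lamina, medulla and into the lobula. `flyeye` compiles a
declarative table of those cell types and their typed connections into a
trainable feed-forward network that keeps this organisation literally:

* **One feature map per cell type, at full input resolution.** There is no
  pooling and no striding anywhere. With the shipped 30-type table and the
  29×29 retinal grid the model holds 30 × 841 = 25,230 artificial neurons
  (reported as ≈25,000).
* **A fixed photoreceptor front-end.** The pooled R1–R6 channel is a single
  weight-shared 3×3 convolution under a hexagonal 6-tap mask — the square-grid
  surrogate for the six photoreceptors viewing neighbouring points in space:
  of the nine taps, the four edge neighbours and one diagonal pair are free,
  and the centre plus the opposite corner pair are frozen at zero. R7 and R8
  are independent 1×1 weight-shared convolutions.
* **Locally connected filters everywhere else.** Downstream connections are
  compiled into locally connected layers (filter weights *not* shared across
  grid positions) of side `rf_columns` ∈ {1, 3, 5} with same-padding; each
  postsynaptic map sums its afferents, adds a per-position bias and applies a
  ReLU. Unshared weights are the natural reading of a connectome in which
  every column owns its neurons; they also make the model sensitive to
  absolute position and size, which is exactly the property the random-zoom
  ablation probes.
* **Structural constraints are validated, not assumed.** A table is rejected
  if it contains self connections within a type (or between lamina monopolar
  L-types), "upstream" edges against the hierarchy ranks, orphan types, or
  photoreceptors that reach no lobula output. Ranks make the graph a DAG with
  photoreceptors as its only sources; lobula output types are ranked by
  nominal axon depth. Evaluation order is topological with a deterministic
  (rank, name) tie-break.
* **Head.** The lobula maps are flattened into a single dense softmax layer.
  The loss is categorical cross-entropy, optimized with Adam (lr 1e-3) under
  early stopping on validation macro F1. The source paper specifies none of
  the optimization details; these are deliberately minimal standard choices
  and all are exposed as arguments.

The shipped table (`default_connectome_path()`) is a documented
approximation assembled from published connectome summaries — 3 photoreceptor
channels, 8 lamina types (L1–L5, C2, C3, T1), 11 modular medulla types
(Mi, Tm, TmY), 8 lobula columnar output types — not a reproduction of any
single dataset. Any table in the same two-section CSV format can replace it.
Motion-pathway neurons (T4/T5), synaptic signs and membrane dynamics are
deliberately out of scope.

## Retinal-resolution preprocessing

* `bottleneck_29()` — bilinear resize to 33×33 then an exact centre crop to
  29×29: the ommatidial sampling budget (⌊√850⌋ = 29).
* `highres_path()` — resize to 256, centre-crop to 224; the crop effectively
  retains the central 158×158 pixels of a native 181×181 chip
  (`effective_extent(181, 256, 224)`; halves round up).
* `bottleneck_then_upsize()` — the bottleneck followed by a bilinear upsize
  to 224×224, so a high-capacity comparator receives an image whose
  information content is fixed at 841 sites.
* `acuity_filter()` — a Fourier-domain simulation of compound-eye acuity:
  each spatial frequency ν (cycles/degree) is attenuated by
  MTF(ν) = exp(−3.56 (Δφ ν)²), with Δφ the minimum resolvable angle (4.8° for
  the inter-ommatidial limit, ≈1.5° for the hyper-acuity estimate) and the
  chip's angular width derived from the viewing distance in body lengths
  (θ = 2 atan(1/(2 d f)); a fly spanning fraction f of the chip means the
  chip spans 1/f body lengths). The DC gain is exactly 1, so mean intensity
  is preserved, and the operation is linear before the final clip to [0,1].
  Following the pipeline of the source study, the filter illustrates the
  acuity bottleneck but is *not* applied inside the re-identification
  pipeline, which uses the plain 29×29 bottleneck.
* `random_zoom()` — the ablation that removes absolute size and proportion:
  independent height/width scale factors from Uniform(0.75, 1.25), with
  centre-crop/zero-pad back to the input size (zero padding preserves the
  centring convention; the original study does not state its padding rule).
  It is applied to training *and* test frames.
* `fit_norm()`/`apply_norm()` — standardization by the mean and (population)
  standard deviation of the training set only; validation and test reuse the
  training statistics.

All resampling is bilinear (the most common default; no resampling kernel is
stated in the source) and centre crops/pads use fixed floor-biased offsets so
every path is bit-reproducible.

## What the synthetic generator emulates — and what it does not

No image data were ever deposited for the study this package models, so
`make_dataset()` stands in for the acquisition design: 20 flies (10 per sex)
filmed 15 min at 16 fps on 3 consecutive days — 14,400 frames per fly per
day — as centred, anterior-up, 181×181 grayscale chips with dorsal, ventral
and lateral viewpoints (uniform thirds by default; the real mix is
unreported).

Each individual draws a latent morphology vector once (body length, thorax
and abdomen widths, abdominal taper, five pigmentation stripe intensities,
wing opacity, leg thickness) from Gaussians around sex-specific means;
females are larger and males carry darker posterior abdominal pigmentation,
with the separation exposed as a `dimorphism` knob. The latent persists for
the life of the individual — that is the identity signal. Days add nuisance:
a multiplicative latent drift (sd 0.02) and an illumination gain drawn once
per fly-day, both derived deterministically from the identity and day.
Frames add pose jitter (rotation sd 6°, translation sd 3 px) and additive
pixel noise (sd 0.05).

The effect sizes were calibrated once, by design, and then frozen:
between-individual variation is dominated by absolute size and shape
(body-length sd 9 px against a day-drift of ~2 px), with subtler pigmentation
differences (sd 0.05 per stripe), so that (a) a plain nearest-centroid
classifier recovers identity across days well above chance but far from
perfectly, (b) the fly-eye model performs well below ceiling at the
scaled-down experiment size, and (c) the absolute-size cue is reliable enough
across days that removing it — which is precisely what the random zoom does —
costs real accuracy. Two failure modes motivated the calibration: with very
mild nuisance the task saturates (macro F1 ≈ 0.999) and every ordering
property becomes vacuous; with identity spread evenly over size and
pigmentation and a large day drift, zoom training acts as a useful
size-invariance augmentation and the ablation no longer lowers the score.
Size-led identity cues also mirror the stated purpose of the zoom ablation:
removing absolute size and shape as cues.

What the generator does **not** emulate: photorealistic texture, walking
trajectories or any behaviour (poses are i.i.d. jitter draws, not
autocorrelated tracks — though splits still never cross the train/test day
boundary, mirroring the by-day generalization claim), occlusions, wing
damage, or arena artefacts. Passing tests therefore demonstrate that the
pipeline extracts persistent morphological identity under day-level nuisance
— they do not certify performance numbers on real video.

## The experiment

`split_dataset()` takes, per fly and training day, the leading 85% of frames
for training and the trailing 15% for validation (the frame counts
12,240/2,160 printed for a 14,400-frame day are the authority; splits are
contiguous in time and never shuffled across the boundary), and the entire
held-out day for testing. `train_reid()` refuses validation data from
outside the training days and classes absent from training. `eval_report()`
scores macro F1 (unweighted mean of per-class F1), per-class precision and
recall, a row-normalized confusion matrix ordered by sex then ascending body
size, and the sex-collapsed F1. `run_experiment()` drives replicates from a
config list or YAML file and aggregates mean ± sd (sd reported as `NA`, not
0, for a single replicate).

Because no deep-learning framework is part of this package's dependency
stack, the off-the-shelf comparator is a ridge-penalized multinomial logistic
regression (glmnet) on flattened chips downsampled to 56×56 after either
224×224 path — a deliberately generic high-capacity baseline run through the
identical preprocessing, used only for the qualitative ordering (high-res
path ≥ bottleneck path).

## Numerical choices and problem sizes

* Initialization: He-scaled Gaussians with fan-in summed over afferent
  receptive fields; biases zero; head Glorot-scaled. A build seed fixes all
  initial weights bit-exactly; a training seed fixes shuffling. Everything is
  single-threaded, so runs are reproducible to the bit.
* Degenerate inputs: zero-variance training pixels, empty test sets, classes
  missing from training, non-square chips for the acuity filter and
  undersized inputs for every resize path raise immediate errors.
* Test problem sizes (the package's own choices for desk-scale runs): the
  headline property uses the scaled-down study condition of 10 flies ×
  3 days × 200 frames/day at native 181-px chips; generator property tests
  (drift monotonicity over 5 seeds, toy two-fly training) render 61-px chips
  through the same size-scaled geometry; the comparator ordering uses
  10 flies × 60 frames/day.
* The full default session (20 × 3 × 14,400 = 864,000 chips) exceeds what
  should be held in memory; `make_dataset()` guards this and supports a
  streamed HDF5 mode and generation-time transforms so only reduced chips are
  stored.

## Known limitations

* The shipped connectome is an approximation; the exact supplementary table
  of the source study was not available. Unit count and topology class are
  reproduced, individual edges may differ.
* Lobula "axon depth" ranks order the output types but no lobula-to-lobula
  edges are shipped by default.
* The comparator is not a convolutional architecture; only the direction of
  the bottleneck effect, not its magnitude, is meaningful.
* Real-video performance (the study reports fly-eye macro F1 ≈ 0.75 on
  20 flies) is not reproducible without the undeposited data; all empirical
  claims in this package are properties of the synthetic benchmark computed
  by its own tests.
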