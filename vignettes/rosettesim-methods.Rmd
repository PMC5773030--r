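---
title: "Simulating Arabidopsis rosettes for leaf-counting networks: models and methods"
author: "rosettesim authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating Arabidopsis rosettes: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rosettesim)
```

## Why simulate plants?

Counting the leaves of an *Arabidopsis thaliana* rosette from a top-down
photograph is a standard image-based phenotyping task, and convolutional
networks do it well — when enough annotated images exist. Annotated plant
images are expensive, and a network trained on one distribution of leaf
counts mispredicts badly on another (dataset shift). `rosettesim`
implements the alternative: a stochastic, parametric L-system model of the
vegetative rosette that can emit unlimited labeled images with any desired
leaf-count distribution, plus the CNN count regressor and the experiment
designs used to probe augmentation, generalization under shift, and
interoperability between real and synthetic data.

## The rosette model

The rosette is a monopodial axis: an apex emits, once per plastochron, a
short internode and one leaf, rotated around the stem relative to its
predecessor. Four empirical functions drive organ geometry:

* `f_lmax(n_norm)` — final blade length against normalized node position.
  The first leaves are small, mid-rosette leaves largest, and the youngest
  again smaller.
* `f_l(t)` — relative blade length against normalized age: sigmoidal,
  `f_l(0) = 0`, `f_l(1) = 1`. The blade length of leaf *n* at age *t* is
  `l_n(t) = X_n · f_lmax(n/20) · f_l(t)`.
* `f_lw(x)` — the blade contour: half-width/length ratio against relative
  midrib position, zero at both ends (ovate, widest just past the middle).
  The blade width is `w_n(t, x) = 2 · l_n(t) · f_lw(x)`: the outline is
  shape-invariant under growth.
* `f_ang(n_norm)` — leaf inclination (degrees pitched from the vertical),
  decreasing with node number so older leaves lie flatter.

Petiole length is a fixed fraction (default 0.5) of blade length; petiole
width is constant (0.02 model units). Lengths are in arbitrary model
units; the render scale policy converts them to pixels, so only relative
sizes matter.

Specimen-to-specimen diversity enters through three draws per plant:

* per-leaf size multipliers `X_n ~ Normal(1, 0.01)`, truncated at zero
  (at sigma = 0.01 the truncation probability is ~1e-23; the truncation is
  a guard, not a modeling choice);
* divergence angles `theta_n ~ Normal(137.5, 2.5)` degrees — the spiral
  phyllotaxis of Arabidopsis with measurement-scale noise;
* a uniformly random development time, realized as a uniform integer leaf
  count on [5, 20]. Drawing the count directly (rather than a continuous
  duration) guarantees the configured range and gives an exact label.

The curves are control-point objects with monotone piecewise-cubic
(Fritsch–Carlson) interpolation — smooth, no overshoot, so grown lengths
can never go negative between control points. The default control points
ship as a plain-text config (`inst/extdata/default_curves.yaml`); they were
drawn to the qualitative shapes above and can be replaced by measured
curves without touching code.

### Choices where the design was open

* **Node normalization.** `f_lmax` and `f_ang` are evaluated at
  `n / 20`, 20 being the model's maximum leaf count. An absolute-node
  domain would work equally; the normalized domain keeps one fixed curve
  domain for every plant size.
* **Time units.** One plastochron is the time unit; a leaf matures in 8
  plastochrons (configurable), and ages clamp to 1 beyond maturation. The
  derivation step is `dt = 0.1` plastochron.
* **Post-emission tail.** After the last emission the plant grows 2 more
  plastochrons, so the youngest leaves are small but visible — mirroring a
  photographed rosette where the newest leaves have just unfolded.
* **Labels.** The label is the number of blade primitives — every emitted
  leaf counts, with no visibility threshold. Ground truth is therefore
  exact and independent of rendering. A render-level guard rejects and
  regenerates the rare sample in which a blade would project to zero
  foreground pixels, keeping images consistent with their labels.
* **Inclination noise.** Only sizes and divergence angles are randomized;
  per-leaf inclination jitter exists in the configuration but defaults to
  zero.

## The L-system engine

The grammar runs on a small timed parametric L-system engine: modules are
symbol + parameter vectors, productions rewrite all matching modules in
parallel each step, a global clock advances by `dt`, and age parameters of
persisting modules advance automatically. Stochastic successors draw from
R's seeded RNG in string order, so derivations are reproducible.
Interpretation is classical bracketed turtle graphics (heading/left/up
frame, degree angles, `[`/`]` push/pop), with drift-guarded
re-orthonormalization of the frame (tolerance 1e-9 after every rotation).
Blades are procedural primitives (placement frame + length + contour) and
are triangulated only at render time, by default 24 segments along the
midrib and 8 across.

## Rendering

The renderer is a deterministic software rasterizer: orthographic nadir
camera, per-triangle flat colors, a z-buffer keyed on height (younger
leaves sit higher on the stem and naturally occlude older ones), 2x
supersampling, and a foreground mask computed at final resolution by
majority rule over subsamples. Non-mask pixels are set to the flat
background color exactly. Per image the renderer draws

* a scale ratio uniform on [0.5, 1]: the projected plant diameter (the
  maximum pairwise distance of the projected geometry) covers between half
  and all of the image side;
* a background: flat soil brown (RGB 110, 80, 55), a uniform random RGB
  color, a 50/50 mixture of the two, or black (the masking convention used
  for cross-domain evaluation);
* a per-leaf brightness jitter (±10%) around the base leaf green.

Real photographs have textured soil, pots, moss and shadows; the synthetic
scenes are deliberately flat-shaded and clutter-free. Cross-domain
evaluations therefore use `apply_mask_black()` on the test images so both
domains present plants on a uniform background.

## Dataset presets

`dataset_preset()` pins three synthetic sets, each 1000 images at
256 x 256 with the 1:2–1:1 scale policy: **S1** (12–20 leaves, soil),
**S2** (5–13 leaves, soil), **S12** (5–20 leaves, mixed backgrounds with
p = 0.5). Labels are written as `filename,leaf_count` CSV; masks as
single-channel PNGs. Every per-sample seed derives from the spec's master
seed by a 32-bit mixing function, so a dataset regenerates bit-identically,
and the loader also accepts externally supplied directories in the
PRL-style layout (RGB PNG + count CSV + `_label`/`_fg`/`_mask` PNGs).
Splits are random, disjoint and exhaustive with `floor(0.8 n)` training
records.

## The counter

Two regression architectures, both tanh-activated, trained on squared
count error with L2 weight decay `1e-4` and a static learning rate `1e-3`:

* **small** — three 5x5 convolutions (stride 1), each followed by 3x3 max
  pooling (stride 2), then a linear output;
* **large** — four convolution/pooling blocks, a 1024-unit fully connected
  layer, then the linear output.

Filter counts are configurable and default to 32/64/64 (+128 for the
large net). The optimizer defaults to Adam (plain SGD available); the
output bias is initialized to the training-label mean so the linear head
starts unbiased. Augmentation applies independent 50% vertical/horizontal
flips, a 10% random-position crop resized back, brightness offsets of
±0.1 and contrast factors in [0.8, 1.2]. Training is deterministic under
a fixed seed and single-threaded BLAS.

Evaluation integerizes predictions by rounding half away from zero and
reports the mean and sd of absolute and signed count differences, the MSE
and R² of the integerized differences, and agreement (% exactly correct);
unrounded variants are kept alongside. R² may be negative — a predictor
can be worse than the truth mean, which is exactly what severe dataset
shift produces.

The convolution/pooling/backpropagation kernels are implemented in
C++ (im2col + BLAS matrix products) inside the package; numerical
correctness is pinned by finite-difference gradient tests.

## Experiment drivers

`run_experiment()` wires the pieces into the three designs: augmentation
(real vs real + S2), generalization (train S12, evaluate on two shifted
ranges with black-background preprocessing), and interoperability (train
synthetic, evaluate on a range-matched set from the other domain, and vice
versa). Real data directories are optional inputs; without them the
drivers run clearly-labeled synthetic stand-in variants rather than
failing, and the reports carry an explicit note. Quantitative results on
real photograph collections require those external datasets and are not
claimed by the package's own test suite.

## Desk-scale verification sizes

The test suite verifies model properties at sizes chosen to keep a full
run comfortable on a single CPU: stochastic moments on ~12,500 pooled
draws (1000 plants), a full 1000-image preset generation at 256 px,
background-policy frequencies on 2000 renders, and learning behavior at
48-px inputs with 8/16/16 filters — a 10-image overfit run (training MSE
below 0.1), a training-set-size sweep over {100, 250, 500, 1000} images
with 3 seeds (median held-out absolute count difference non-increasing in
size), and a trained-on-uniform model beating the best constant predictor
on held-out data. These reduced sizes change runtime, not the properties
being tested; the full-scale protocol (256 px, 32/64/64 filters, 100
epochs with early stopping) is the package default.

## Known limitations

* Blade outlines are smooth ovate surfaces: no serrations, sinuses, or
  curvature out of the blade plane.
* Backgrounds are flat colors; real soil texture, trays and moss are out
  of scope, which is why cross-domain tests mask backgrounds to black.
* Cotyledons are not modeled; the count range refers to true leaves.
* The camera is exactly nadir and orthographic; real benchmark images are
  near-nadir perspective photographs.
* Passing synthetic-only tests demonstrates the pipeline and the model's
  internal consistency, not performance on real photographs.
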