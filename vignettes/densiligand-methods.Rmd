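---
title: "Methods: density-map ligand recognition in densiligand"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: density-map ligand recognition in densiligand}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, conventions and numerical choices
behind `densiligand`: what each stage assumes, which parameters matter,
and where the design was genuinely open. The companion README shows the
user-facing workflow; here we concentrate on the *why*.

## The voxel model

Every grid in the package is a lattice of voxel **centers**: voxel
`(i, j, k)` (1-based) sits at `origin + (i-1, j-1, k-1) * spacing`. This
single convention is used by the MRC reader/writer, the resampler, the
point-cloud conversion and the samplers. MRC files may store their data
axes in any `MAPC/MAPR/MAPS` permutation; `read_map()` normalizes to
x-fast order on read, and `write_map()` always emits the normalized
convention, so round trips are bit-stable for float32 data. Only mode-2
(float32) maps are accepted — other modes are a format error, not a silent
conversion.

## Sigma thresholding and its statistics

`threshold_xray()` contours a difference map at `mean + n_sigma * SD` with
`n_sigma = 2.8` by default. The mean and SD are the *population* moments
over **all** voxels of the supplied grid. Crystallographic sigma scales
are conventionally defined over the full map; nothing in the interface
depends on unit-cell bookkeeping, so callers who prefer asymmetric-unit
statistics can pre-crop. Thresholding is idempotent once the statistics
are frozen; re-applying the operation to its own output recomputes
statistics of a sparser field and is deliberately *not* a no-op.

## CryoEM normalization

CryoEM maps lack a common value scale, and refinement-time masking loads
the histogram with a spike of (near-)zero voxels whose mass depends on the
arbitrary box size. The normalization therefore works in three steps:

1. **Zero-inflation reduction** drops all values within
   `median_window_sd = 0.5` population SDs of the median. This band
   contains the masking spike. The reduced collection is used *only* to
   choose the threshold; the contour is applied to the original map.
2. **Quantile thresholding** places the contour at the empirical quantile
   `Φ(2.8) ≈ 0.9974` of the reduced values. A quantile, unlike a σ
   multiple, is meaningful for the non-normal histograms that remain
   after masking. The estimator is linear interpolation between order
   statistics (`stats::quantile` type 7) — fixed and documented because
   estimator choice visibly shifts thresholds on small maps.
3. **Voxel rescaling** multiplies the thresholded map so its lowest
   non-zero value equals a resolution-keyed reference (the average lowest
   non-zero value of thresholded X-ray blobs at that resolution). The
   implementation divides by the current minimum before multiplying by
   the reference so the pinned value is exact in floating point.

Two consequences are asserted as invariants: on a zero-inflated map the
post-removal threshold is at least the naive one (the removed band can
only shift the far-tail quantile up), and the normalized map contains no
value strictly between zero and the rescaled threshold.

On a map with *no* zero inflation the removal step still excises a
symmetric central band (about 38% of a normal body), which moves the
0.9974 far-tail quantile by a few percent — the tests bound this at 10%
relative rather than pretending exact agreement.

**The reference table.** The per-resolution reference values are not a
published constant, so the shipped `default_rescale_table()` is computed
from the package's own synthetic X-ray blob generator (bins 1.0–4.0 Å in
0.5 Å steps, left-closed/right-open, last bin closed; frozen from
`build_rescale_table(seed = 20240101)` and regenerable by the same call).
These synthetic defaults make the pipeline self-contained; production use
should substitute a table built from real X-ray blobs.

## Blob extraction and quality filters

Connected components of positive voxels use 26-connectivity: density
blobs routinely touch only diagonally, and 6-connectivity would shatter
them. A ligand split into several components by thresholding yields
several blobs; merging by residue identity is the caller's decision. The
X-ray filters are *rejection* rules joined by "or" (any trigger rejects),
with RSZD's bound inclusive (exactly 6.0 rejects). The cryoEM filters
require Q-score ≥ 0.6 (inclusive: 0.6 passes) and volume strictly greater
than 2.14 Å³. Metrics that are absent skip their test rather than reject —
cryoEM blobs have no RSCC/RSZD, and rejecting on missingness would empty
the set.

## Point sampling

All strategies cap the cloud at `max_p` points (default 2000). The
default, uniform sampling with maximum selection, partitions the blob's
bounding grid into `N^3` meta-voxels (each face divided by `N`,
non-divisible dimensions zero-padded at the high-index corner so original
indices never move) and keeps the maximum-density point of each occupied
meta-voxel, with its original coordinates and density. `N` starts at 1
and increases by steps of 1 while the occupied-meta-voxel count stays
within `max_p`; if `N + 1` overshoots, `N` is kept.

One subtlety the tests uncovered: the occupied count is **not** monotone
in `N`. The per-`N` padding makes the meta shape `ceiling(d / N)`, which
can repeat across consecutive `N` and occasionally *merge* occupied
blocks as `N` grows (e.g. extent 9 with occupied 0-based indices {2, 3}:
two blocks at `N = 3`, one at `N = 5`). The incremental search is
therefore implemented literally as specified rather than as a binary
search that would assume monotonicity.

Ties within a meta-voxel resolve to the lowest linear voxel index —
determinism over elegance. The surface strategy defines the shell by
6-neighborhood emptiness (a face-exposed voxel is surface). The
clustering strategy returns k-means centroids, which are synthetic
points; their density is the mean density of the cluster's members, since
no original value is attached to a centroid.

## Ligand grouping

Ligands that produce indistinguishable density are merged into groups by
a graph signature: heavy-atom count, cycle rank
(`bonds − atoms + components`), the multiset of `(atomic number, degree)`
pairs together with the multiset of bonded atomic-number pairs, and the
multiset of chirality flags. This is a necessary-but-not-sufficient
isomorphism invariant — two non-isomorphic graphs can in principle
collide — chosen deliberately: it is stable, fast, needs no canonization,
and is invariant under relabeling (property-tested over random
permutations). Chirality is an unordered multiset because per-center
correspondence cannot be established without 3D coordinates. Groups with
at least 100 instances (inclusive) are named; everything else maps to
`rare`. The shipped 219-label catalog (`provisional_catalog_219()`)
carries placeholder names purely to fix the head size and ordering, and
is documented as synthetic.

## The classifier

The network follows the feature-pyramid pattern used in sparse-voxel
place recognition, adapted to ligand classification:

* **Input**: points quantized to integer cells of 0.2 Å (the canonical
  grid), duplicate cells merged by maximum density, feature = density.
  Coordinates are shifted to a zero minimum and sorted, which makes the
  forward pass exactly invariant to input point order and to translations
  by whole cells. It is *not* rotation invariant; rotation augmentation in
  the synthetic dataset is what exposes the model to orientation variety.
* **Bottom-up**: three convolution blocks of increasing receptive field —
  a 3³ stride-1 convolution, then two stages of 2³ stride-2 downsampling
  followed by 3³ stride-1 convolution, each block gated by Efficient
  Channel Attention (a shared 1D convolution over the channel-mean
  descriptor, sigmoid-gated, no channel reduction).
* **Top-down**: the deepest features return through a 2³ stride-2
  transposed convolution and are added to a 1×1 lateral projection of the
  mid-level features.
* **Head**: NetVLAD aggregates the fused per-point features against
  learned cluster centers (soft assignment, residual sums,
  intra-normalization, global L2), followed by two fully connected layers
  and a softmax.

The published architecture's exact widths and cluster counts are not
available, so defaults are small and overridable
(`channels = c(32, 64, 128)`, 16 clusters; `train_model()`'s built-in
default is smaller still, `c(16, 32, 64)` with 8 clusters, sized for
desk-scale experiments). Density features enter raw — after the map-level
normalizations the scale is already harmonized, and an extra per-blob
normalization would erase the brightness cues that distinguish heavy
atoms.

All forward/backward passes are hand-written matrix algebra. Correctness
is enforced by a finite-difference gradient check over every weight array
in the test suite, plus exact invariance tests (point order, whole-cell
translation). Training uses Adam with cross-entropy, per-epoch shuffling,
gradient accumulation (`grad_accum` samples per step) and optional
per-class oversampling; a fixed seed makes runs bit-reproducible on one
machine. Batch normalization is omitted — at batch size one it degenerates
to instance statistics, and the attention-gated blocks train stably
without it at these scales.

## Evaluation protocol

The rank of the true label is `1 + #(classes with strictly greater
probability)`, ties broken by catalog order, making every metric a pure
function of its inputs. The Brier score is the *verbal* definition — mean
squared probability error of the correct class, `mean((1 − p_truth)^2)` —
not the multi-class sum-over-classes variant; the two differ by roughly a
factor of two on calibrated classifiers and only this one lies in [0, 1].
Macro recall averages over the classes actually present in the truth set,
excluding undefined recalls. The grouped stratified split assigns whole
deposits (groups) to one side, greedily by class frequency and group
richness against per-class targets; disjointness is re-asserted on every
call as a hard invariant. Stratified k-fold assigns whole groups to folds
greedily (largest first, to the fold poorest in the group's dominant
class). Exact stratification under grouping constraints is NP-hard;
greedy determinism was preferred over stochastic optimality.

## The synthetic generator

Synthetic blobs are sums of atom-centered isotropic Gaussians with
σ = `peak_width_rule × resolution` (default 0.4 Å per Å — at 2 Å
resolution bonded-atom peaks merge while well-separated atoms stay
distinct, mimicking how features coalesce as resolution degrades) and
amplitude proportional to the pseudo atomic number (heavier atoms are
brighter). Maps add i.i.d. Gaussian background noise; cryoEM-kind maps
additionally force a seeded fraction of voxels to exactly zero, emulating
masking — exactly the contrast the zero-inflation step targets. The
generator makes no claim to physical accuracy (no scattering factors, no
B-factors, no solvent model); what passing tests demonstrate is that the
pipeline's *mechanics* are correct, not that the classifier's accuracy on
synthetic shapes transfers to real deposits.

The 3-class benchmark (`make_classification_dataset`) renders tetrahedron,
chain and ring templates with random rigid rotations, 0.1 Å atom jitter
and noise, then thresholds and uniformly samples each blob. The classes
are geometrically separable by construction (a nearest-centroid baseline
on two principal-axis shape features already separates them), so held-out
label recovery by the network is a meaningful functional test of the whole
stack. The shipped experiment sizes — 90 blobs, `max_p = 512`, 30 epochs,
the small default architecture — were chosen so the full benchmark trains
in about a minute on one CPU core while still reaching perfect held-out
accuracy.

## Known limitations

* The group signature is weaker than graph isomorphism; pathological
  collisions are possible.
* The rescale-table defaults are synthetic stand-ins, not values derived
  from real X-ray blobs.
* The network is not rotation invariant; orientation robustness comes
  only from training-time augmentation.
* The NPZ reader supports the subset of dtypes the blob format uses
  (little-endian floats, 32/64-bit integers, fixed-width unicode
  scalars), plus zip64 archives as written by `numpy.savez`.
* `render_map` places blobs by rejection sampling; extremely crowded
  boxes fail with a placement error rather than overlapping silently.
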