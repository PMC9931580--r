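---
title: "Methods: spatial single-cell analysis of multiplexed tissue images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spatial single-cell analysis of multiplexed tissue images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(imcniche)
```

This vignette is the package's own account of its models and conventions:
what each stage computes, which parameters matter and why their defaults
are what they are, which design points were genuinely open and how they
were settled, and what the synthetic benchmarks do and do not demonstrate.

## Data model

An acquisition is a `channel_stack` — a channel × height × width array of
non-negative counts at a known pixel size (1 µm by default, so a
1000 × 1000 image is a ~1 mm² core). Coordinates are pixel units,
origin top-left, x = column, y = row, 0-based; a cell's centroid is the
unweighted mean of its member pixel coordinates, matching label-mask
regionprops conventions. Segmentation itself is out of scope: the
pipeline consumes an integer label mask produced upstream (or by the
built-in generator). Stacks and masks round-trip through 32-bit integer
TIFF bit-exactly; IMC measurements are counts, and the integer path is
the only lossless one through the available TIFF writer. Channel names
travel in a plain-text sidecar (`<image>.tiff.channels.txt`); when it is
absent, taking page order on faith requires an explicit
`match_by_order = TRUE`, because silent channel-order mismatches are the
dominant failure mode for multiplexed imaging data.

## Mask curation

Each lineage marker channel is reduced to a binary foreground mask in
six steps: optional percentile saturation, 3 × 3 median filtering (edge
replication), 1-D k-means quantization of pixel intensities into 6
levels, selection of the brightest `foreground_level` groups, removal of
connected components (8-connectivity) smaller than `min_blob_area`, and
an optional adaptive local-mean refinement.

Conventions the source procedure leaves open, and how they are fixed
here:

* **"Up to a particular level" counts from the brightest group.**
  Antibody signal is bright-positive; the group-centre order is recorded
  so the opposite convention is a one-flag change
  (`select_foreground(..., brightest = FALSE)`).
* **Default `foreground_level = 5`.** On stained channels the
  exponential-like background collapses into the dimmest of the six
  k-means groups while the lognormal signal spreads over the remaining
  five. Empirically (see `test-mask_curation.R`), keeping the top five
  groups recovers > 99 % of a planted signal region at ~0 false-positive
  rate, whereas keeping only three recovers ~68 %. The level remains a
  per-marker panel parameter.
* **Adaptive refinement combines by intersection.** The step exists "to
  further refine" a mask, i.e. to remove noise, so the result is always
  a subset of its input; union is available behind a flag. The local
  mean is taken over a square window of side `2⌊min(dim)/16⌋ + 1` and a
  pixel passes when its value exceeds `(1 − sensitivity) ·
  local_mean` — higher sensitivity admits more foreground; the default
  sensitivity is 0.4.
* **Contrast enhancement is pure saturation.** Values outside the
  `low_pct`/`high_pct` percentiles are clipped; nothing is rescaled,
  because the downstream quantization is scale-free and rescaling would
  undo the point of clipping the outliers.
* **Degenerate quantization.** Fewer distinct intensities than groups
  yield one level per distinct value (with a warning); a constant
  channel has no contrast and curates to an empty mask.
* **Determinism.** Quantization uses k-means++ seeding with 10 restarts
  under a derived seed. For channels above 10⁵ pixels the restarts are
  evaluated on a deterministic stride subsample and the best
  initialisation is polished by full-data Lloyd iteration — same
  fixed-point, a fraction of the cost, still bit-reproducible.

## Lineage assignment

Every pixel p carries a presence vector E(p) over the curated
lineage-marker masks; a cell's majority vector M is the per-marker sum of
E(p) over its pixels (exact integer counts). A lineage's vote is the
*maximum* over its defining markers — not the sum, so co-staining pixels
are not double-counted — and the largest vote wins, with ties resolved
by rank priority (the hierarchy's order). An all-zero vote is
`Undefined`; such cells keep their expression summaries and participate
in every spatial analysis as their own category, because cells outside
the panel still occupy space. The hierarchy is a required configuration:
the appropriate priority order depends on the panel, and the simulated
panels simply list types in configuration order.

Subphenotype flags are positivity calls on the same majority vectors: a
cell is marker-positive when the marker's vote covers at least a
fraction (default 0.25) of the cell's area — robust to mask speckle
while catching partial membrane staining. The default rules implement
the brain-TME scheme (P2Y12⁺ macrophages are microglia, P2Y12⁻ are MDMs;
CD163 splits M2-like from M1-like; MPO⁺ flags the neutrophil-like
subset). Expression summaries are raw per-channel mean pixel values —
no transformation — and the 95th-percentile normalization plus
cluster-mean z-scoring exist for display only.

## Interaction and avoidance tests

Two cells interact when their centroids are within `radius_um`
(default 6 µm). For an ordered pair (A, B) the statistic is the mean
number of B-neighbours per A-cell; the null shuffles phenotype labels
over all cells of the image with positions (and hence the graph) fixed.
Because the label multiset is preserved, the per-A-cell mean and the raw
directed edge count differ by a constant, so permutation comparisons are
carried out on exact integers. One-tailed p-values use the add-one
estimator (1 + #extreme)/(n_perm + 1), which cannot return zero; calls
are *interact* when p_interact < 0.01, *avoid* when p_avoid < 0.01
(the two cannot both fire at any α ≤ 0.5), otherwise *ns*. Pairs whose
types are absent from an image are excluded, not errored. The cohort
heatmap entry for (A, B) is the fraction of eligible images called
interact minus the fraction called avoid, read row-to-column; the matrix
is intentionally not symmetrised because the statistic is directional.

Conditional contrasts split focal-type cells into "interacting"
(≥ 1 partner neighbour) and "avoiding" (none) under the same 6 µm
adjacency, then compare a per-cell statistic — a marker mean, or the
Ki67:CC3 proliferation/apoptosis ratio guarded by a pseudocount equal to
the smallest positive CC3 mean in the image (fallback 10⁻³). Density
categories for a flagged population are `none` (0 cells), `low`
(up to 5 cells per mm²) and `high` (≥ 6 per mm²), with zero-cell images
displayed as 1 on log axes.

## Cellular neighbourhoods

A cell's window is the frequency vector of the types of its N nearest
other cells (the index cell is excluded — "the N closest cells *to* a
cell" — but an `include_self` flag provides the other convention).
Frequencies rather than counts are clustered so models with different N
share one space. Ties at the N-th distance break by cell order, purely
for reproducibility. Windows never cross images.

Windows pooled over the discovery images are clustered by mini-batch
k-means — k-means++ seeding, then Sculley-style per-centre running-mean
updates, here applied batchwise in closed form so the result is exactly
the sequential update at a fraction of the interpreter cost — with
defaults batch 100, seed 0;
K = 1 short-circuits to the grand mean, which is the exact optimum.
Margin-type images can be excluded from discovery and labelled afterwards
with `predict_cn()`. Per-image prevalence is normalized to sum to 100 %,
patient-level prevalence averages duplicate cores, and stratification
splits at prevalence z ≥ 0 vs z < 0 (or at the median; on symmetric
distributions the two coincide). CN maps are rendered as the discrete
Voronoi tessellation — every pixel takes its nearest centroid's label —
which is the exact pixel-grid Voronoi diagram and needs no
computational-geometry dependency.

## Hybrid phenotype clustering

Selected cells (e.g. monocytes/macrophages over the canonical 14-marker
list) are embedded with exact t-SNE (perplexity 30, early exaggeration,
deterministic given a seed; quadratic cost, intended for up to a few
thousand cells). Clustering then proceeds: DBSCAN with eps 3 and
minPts 30 on the 2-D embedding (the radius is quoted in plot units,
which is why the embedding, not the 14-dimensional feature space, is the
default substrate; a flag switches); every DBSCAN cluster except the
largest is kept as a final cluster, the largest — the "big group" whose
size boundary the source leaves unstated — is subsampled 1-in-10 and
re-clustered by spectral clustering (symmetric kNN affinity with k = 15,
symmetric-normalized Laplacian, k-means on the row-normalized
eigenvector embedding) into a user-chosen number of clusters — there is
no principled default for this number, so it is a required parameter;
finally a 5-nearest-neighbour
classifier trained on all labelled points assigns every remaining cell a
label. Labelled points are never re-predicted, which makes the extension
step idempotent and the final labelling total by construction.

## Cohort statistics and survival

Test selection is a pure function of the data: for two groups,
Shapiro–Wilk at 0.05 on each group chooses between Student's t-test and
Mann–Whitney, with the t-test forced when both groups reach n ≥ 30
(the customary large-sample override; the threshold is configurable
because the practice is cited without a number); more than two groups go
to one-way ANOVA with Tukey comparisons; 2 × 2 tables use Fisher's exact
test. Survival uses Kaplan–Meier estimates and the log-rank (Mantel–Cox)
test via the survival package, with the hand-computable O − E form
verified independently in the tests. Patients contributing several cores
enter survival analyses exactly once: per-image features are averaged
per patient first. Patients without an observed death are treated as
censored at last follow-up — the source wording ("estimated using the
date of their last known follow-up") is ambiguous between censoring and
an imputed event, and censoring is the conservative reading; the data
model therefore requires an explicit event flag rather than inferring
one.

## Synthetic tissue model

The generator is the pipeline's ground-truth substrate. Cells are points
in a width × height window (defaults 1000 × 1000 px ≈ 1 mm² at 1 µm/px,
2000 cells, within the 1000–5000 cells per core typical of IMC).
Types draw from configured proportions; planted structure comes in three
forms:

* **Attraction** (Thomas process): partner cells are offspring of shared
  parents with Gaussian displacement at the configured scale (default
  4 µm).
* **Avoidance** (Matérn-II-style): partner cells falling within a
  hard-core distance (default 8 µm) of the other type are thinned, so
  realized counts drop — which is what hard-core interaction does.
* **Neighbourhood regions**: rectangular zones with their own type
  compositions, the ground truth for CN recovery.

Rendered images pack cells as non-overlapping discs (radius 3–5 px,
default 4; conflicting cells are jittered then dropped, erroring if
fewer than half survive) and draw each marker channel as integer counts:
exponential background (mean 0.3) everywhere plus lognormal signal
(meanlog 3, sdlog 0.4 — median ≈ 20 counts) inside cells positive for
the marker, mimicking the skew of IMC count data. Because packing keeps
centroids ≥ 2r + 1 px apart, the 6 µm graph on rendered images is empty
at the default radius; interaction analyses therefore run on the
unpacked point-process stage (`generate_cells()`, `null_image()`), whose
geometry is the one the permutation test sees in real data. Survival
times are exponential with rate `base_rate · exp(β · z)` where z is the
standardized planted feature (default β = ln 2 per +1 SD), censored at
an administrative horizon.

Everything is driven by one master seed through `derive_seed()`, which
hashes the seed with stream tags (image id, stage) so results are
bit-reproducible and independent of execution order.

## What the benchmarks show — and what they do not

The acceptance-style checks (also re-run by `scripts/acceptance.R`) use
these problem sizes, chosen to exercise the stated study conditions at
desk scale: 500 null images of 500 cells and 3 types with 1,000
permutations each for calibration; 100 images per power scenario
(attraction at 4 µm with 500 cells; hard-core avoidance at 8 µm with
3,000 cells — at 500 cells/mm² the 6 µm graph is too sparse for *any*
avoidance call, since the null probability of zero A→B edges already
exceeds 0.01); 20 rendered 400 × 400 px images of 400 cells and 8
lineages for end-to-end phenotyping; 40 images of 300 cells with four
planted quadrant compositions (0.91 dominant-type share, so that even a
3-cell window carries the home region's majority ~97 % of the time) for
CN recovery across N ∈ {3, 5, 10, 20, 30}; three planted groups of
150–250 points for hybrid clustering; and 200 replicates of a 32-patient
cohort for log-rank calibration and power — with a bimodal planted
prevalence (two 16-patient groups), mirroring the 16 + 16 long- vs
short-term survivor design, so the z-split recovers the planted groups
rather than dichotomizing a continuum.

The generator emulates the *statistical* structure the analyses assume —
clustered and repelled point patterns, niche regions, marker-defined
lineages with skewed count noise, survival linked to a spatial feature —
but not real tissue: cells are discs, not morphologies; markers are
conditionally independent given type (no spillover, no co-expression
gradients); regions are rectangles; and staining artefacts, hot pixels
beyond what the median filter removes, and batch effects are absent.
Passing these benchmarks therefore demonstrates that the implementation
is correct and calibrated on data satisfying its assumptions; it does
not certify performance on any particular real cohort, where panel
design, segmentation quality and staining variability dominate.
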