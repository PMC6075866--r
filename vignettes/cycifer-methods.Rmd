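---
title: "Methods: from cyclic immunofluorescence tiles to single-cell spatial statistics"
author: "cycifer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from cyclic immunofluorescence tiles to single-cell spatial statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Overview

Tissue-based cyclic immunofluorescence (t-CyCIF) builds a high-plex image of
an FFPE section by iterating rounds of four-channel staining, imaging and
fluorophore inactivation. Channel 0 of every cycle carries a DNA stain
(Hoechst/DAPI), re-imaged each round; the three remaining channels carry
antibody markers that change from cycle to cycle. Computationally the assay
is a chain: raw tiles are shading-corrected, background-subtracted, stitched
into per-cycle mosaics and rigidly registered onto the first cycle's nuclear
image; nuclei are segmented once on that reference and quantified across all
cycles; and the resulting single-cell table feeds cycle-level quality
control, mixture-model phenotyping and spatial statistics.

`cycifer` implements that chain end to end and pairs it with a synthetic
specimen generator with exact ground truth, so every stage is testable
without external data. This vignette records the models, the parameters
that matter, and the design decisions taken where the procedure was
genuinely open.

# The synthetic specimen

`generate_phantom()` places nuclei by dart throwing under a hard-core
constraint (centers at least 1.5 times the larger radius apart), which
matches the assumption behind watershed splitting that nuclei are distinct
objects. Defaults describe a dense 10X field: about 500 cells on a
480 x 480 px canvas at 0.65 um/px, nuclear radii ~N(5, 0.4) px. The canvas
is partitioned into a stromal and a tumor half-plane; each cell draws an
expression cluster (immune-like, tumor-like, stromal-like) with
region-dependent frequencies, and marker intensities are lognormal with
per-cluster medians — the standard model for antibody-intensity
distributions. The stromal marker aSMA is additionally up-weighted
eight-fold in the stromal region, giving the smooth regional contrast the
region-assignment step relies on.

Cell dropout emulates the progressive tissue loss seen over staining
cycles: a binomial fraction of cells (default 15% across ten cycles)
receives a detachment cycle, preferentially in low-density neighbourhoods
(sampling weight `(1 + neighbours)^-1`), mirroring the observation that
loss concentrates in regions of low cellularity.

`render_cycles()` converts the phantom to tiles. Cells are rendered as
flat-core disks with a Gaussian edge skirt (`sigma = 0.75` px, truncated at
3 sigma, core radius `max(r - 0.75, r/2)`). The profile's half-maximum sits
at the nominal radius, so intensity thresholding recovers the true disk
area — a pure Gaussian kernel was rejected because its binarized area
depends strongly on where the threshold falls (an Otsu cut recovered only
~60% of the nominal area), which would make the truth radii meaningless.
Each cycle applies a rigid stage offset to the scene (rotation about the
mosaic center, then translation), drops detached cells, adds a
cycle-decaying autofluorescence background (geometric decay, default 150
counts decaying by 0.6 per cycle — background bleaches with the signal),
multiplies by a radial vignette (mean exactly 1), and adds Poisson shot
noise plus Gaussian read noise before 16-bit quantization. What the
generator does *not* emulate: real tissue texture, spectral bleed-through,
out-of-focus light, non-rigid deformation, and antibody-specific staining
artifacts — passing tests therefore demonstrate correctness of the
computational chain, not robustness to every property of real tissue.

# Image preparation

**Shading.** The flat-field is estimated retrospectively as the per-pixel
median across at least eight same-channel tiles, Gaussian-smoothed
(sigma = tile width/16, replicate boundary) and renormalized to mean 1.
The median rejects sparsely occurring bright cells; the estimator degrades
when a large fraction of distinct tile layouts is cell-covered at the same
pixel, so many fields of view (or lower cell density) sharpen it.
Correction divides out the flat-field after subtracting an optional
darkfield (per-pixel 1st percentile).

**Background.** Rolling-ball subtraction is implemented as grayscale
opening with a disc structuring element (default radius 50 px), equivalent
to the classic ImageJ algorithm up to its internal downsampling. Optional
unsharp masking (`image + amount * (image - blur)`) is applied after
background subtraction when enabled; the processing order is not dictated
by the assay and is configurable.

**Stitching.** Neighbouring tiles are aligned by windowed, mean-removed
cross-correlation of their nominal overlap strips, with the peak refined on
a 50x locally upsampled inverse DFT of the cross-power spectrum. Plain
(unwhitened) correlation is used deliberately: on narrow, noise-dominated
strips the whitened (phase-correlation) peak localizes to only ~1 px, and
the resulting quadrant misplacements masquerade as a spurious mosaic
rotation of a few tenths of a degree; the unwhitened peak localizes to
~0.05 px. Pairwise offsets are reconciled by least squares over the tile
graph (anchored on the first tile) and tiles are composited with linear
feathering; featureless overlaps (normalized correlation peak below 0.2)
fall back to nominal offsets with a provenance warning.

**Registration.** Per-cycle nuclear mosaics register to cycle 1 by the
same correlation estimator; rotation is recovered by a grid search over
±2 degrees (step 0.05 degrees) scored by the correlation peak after
de-rotation, followed by golden-section refinement. On default synthetic
data the full chain recovers stage offsets to ~0.02 px and ~0.02 degrees.
All channels of a cycle are then resampled through that cycle's transform
(bilinear; out-of-frame pixels are flagged invalid and excluded
downstream). Bilinear interpolation is a documented small bias (<2%) for
integrated intensities of sharp-edged objects.

# Segmentation and quantification

Nuclei are binarized by a global Otsu threshold with small-hole filling
(<10 px) and speck removal (<20 px), then split by seeded watershed: seeds
are local maxima of the Euclidean distance transform with a minimum
separation equal to the expected nuclear radius (default 5 px), grown
through the mask by a purely spatial propagation, so touching nuclei split
along the equidistance line. Cytoplasm derives from centripetal expansion
(3 px at 10X, 6 px at 40X) in which all nuclei expand together and
contested pixels go to the nearest nucleus — an interpretation of
"expansion until the cell boundary", since no membrane marker constrains
the true boundary. Segmentation runs once on the reference-cycle nuclear
mosaic and the labels apply to every cycle, as the cycles share registered
coordinates.

Quantification reports mean and integrated (summed) intensity per cell for
nucleus, cytoplasm and whole cell in every (cycle, channel), using only
pixels valid in that cycle; `integrated = mean x area` holds exactly when
a cell is fully valid. Border-touching cells and cells with >50% invalid
pixels in any cycle are flagged `valid = FALSE` rather than dropped, so
integrity counts stay complete.

# Cycle QC

Tissue integrity is the per-cycle nucleus count normalized to cycle 1
(values slightly above 1 arise from segmentation fluctuation); matched
retention uses greedy mutual-nearest-neighbour centroid matching within a
radius defaulting to the median nuclear radius. Fluorophore-inactivation
folds are background-corrected ratios of median cell intensities (medians
resist segmentation outliers). Dynamic range is `log10(P95/P5)` of an
intensity sample (log base chosen as 10; the convention is unstated in the
assay literature), which rises as background shrinks — the mechanism behind
dynamic range improving with cycle number. The overlap score
histogram-estimates both samples as unit-area densities on a shared
percentile-trimmed support (0.1–99.9%, 100 bins) and returns the
trapezoidal integral of the pointwise minimum over that of the pointwise
maximum. This min/max envelope reading of "overlap area over total area"
was chosen because it yields the documented [0, 1] range with 1 for
identical distributions; scores above 0.8 classify as high concordance,
0.6–0.8 (inclusive) moderate, below 0.6 low. Nominal optical resolution
uses `0.61 lambda / NA` (widefield) and `0.4 lambda / NA` (confocal).

# Phenotyping

Intensities are variance-stabilized by `asinh(x / 5)` by default (log1p
available); the cofactor 5 is the common imaging/flow-cytometry choice.
Channels are rescaled to their 1st–99th percentile window and clipped to
[0, 1]; whether clustering should run on transformed or raw intensities is
not fixed by the assay, so the transform is configurable, and cell area
plus nuclear-stain intensity can be appended as features.

The Gaussian mixture is fitted by EM with full covariances, k-means++
initialization, diagonal regularization 1e-6, convergence at a relative
NLL change below 1e-7 (cap 500 iterations), and 30 restarts keeping the
best likelihood; the NLL is asserted non-increasing across iterations.
Model selection reports the NLL curve with successive improvements and
second differences — the quantities one inspects to place the inflection
by eye — but the automated choice minimizes BIC. A raw
max-second-difference rule was rejected after it reliably chose k = 2 for
any well-separated mixture: the first split always produces the largest
likelihood gain, so the raw curvature peaks at the start of the curve
rather than at the true component count. BIC encodes the same
"diminishing returns" logic with an explicit penalty and recovers the
true k on separated mixtures while the full curve remains available for
manual override.

The 2-D embedding uses exact t-SNE with the classic cytometry settings
(perplexity 30, learning rate 500, early exaggeration 4 for the first 100
iterations), single-threaded for determinism. Embeddings are treated as
qualitative; quantitative claims rest on the mixture model.

# Spatial statistics

Fields are regular grid cells (floor convention at boundaries). The
non-parametric Shannon entropy of a field samples 1000 cells without
replacement, rescales the intensity vector to unit L2 norm so the squared
entries form a probability vector, and returns `-sum(s^2 ln s^2)` — 0 for
a single expressing cell, `ln(1000)` for uniform expression. The L2
normalization is the reading that makes the summand a probability; fields
with at most 1000 cells are excluded, and per-field values are normalized
by the specimen-wide entropy.

Marker positivity gates threshold log-transformed cell means by Otsu
(positivity thresholds are assay-specific and never published), with a
fixed-threshold alternative; composite gates are conjunctions. Tumor and
stroma are delineated by Gaussian-kernel smoothing (bandwidth 50 px) of the
stromal-marker intensity onto a grid and an Otsu split of the smoothed
field; degenerate fields leave all cells in one region with a warning.

The kNN density at a grid point is `(k - 1) / (n pi d_k^2)` with k = 4
(about a 10 um smoothing window at typical cell spacing) and `d_k` floored
at half the grid spacing. The `k - 1` numerator is the classical
unbiasedness correction: with `k` in the numerator the estimator
overshoots a uniform density by ~E[k/(k-1)] (measured +24%), and since
only ratios and products of densities are used downstream the constant is
free. A caveat documented here because a test exercises it: duplicating
every point in place inflates the estimate by `E[d_k^2/d_{k/2}^2]/2
(≈1.5–1.7)`, not exactly 2, because duplicated points violate the Poisson
assumption behind the estimator.

Co-occurrence normalizes each population's density to a probability over
each region's grid points separately — removing the effect of absolute
cell numbers per region — and multiplies them pointwise; fold enrichment
compares region means and the hotspot mask marks the top decile of the
product map. Bootstrapped counts resample cells with replacement within a
region (100 rounds) and report the mean and `sd/sqrt(n_boot)` of
gate-positive counts.

# Orchestration, determinism and problem sizes

`run_pipeline()` executes simulate → prep → segment → qc → phenotype →
spatial, each stage reading and writing only documented files (16-bit
TIFF, CSV with 17-significant-digit floats, JSON with sorted keys), with
one seed per stochastic stage and MD5 hashes of all artifacts in the run
manifest. Two runs with identical configuration and seeds produce
hash-identical artifacts; this is asserted in the test suite. Label
images are written as 16-bit TIFF (counts stay far below 2^16).

Default problem sizes — a 2 x 2 tile grid of 256 px tiles (12.5% overlap),
three cycles, ~500 cells — were chosen so a full run, including mixture
model selection with 30 restarts and an exact t-SNE, completes in about a
minute on one CPU while exercising every stage at realistic density. Test
fixtures use the same generator at smaller sizes. Simulation-based checks
(dropout recovery, mixture recovery, co-occurrence direction) run over
multiple fixed seeds and compare against binomial or multinomial error
bands rather than point values.

# Known limitations

Segmentation is nuclear-only, so irregularly shaped or stacked cells can
exchange signal between neighbours ("contamination"), and the cytoplasm
ring is a proxy rather than a membrane-bounded compartment. The stitcher
and shading estimator are minimal equivalents of the dedicated external
tools used for production mosaics (ASHLAR, BaSiC) — adequate for the
synthetic regime and the tested contracts, but without their tile-graph
robustness or low-rank illumination modelling. Registration is rigid by
design; non-rigid tissue deformation is out of scope. The t-SNE layout,
as always, is not a quantitative map.
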