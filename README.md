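# cycifer

Tissue-based cyclic immunofluorescence (t-CyCIF) produces high-plex images
of FFPE tissue sections by repeating rounds of four-channel staining,
imaging and fluorophore inactivation: channel 0 of every cycle carries a
DNA stain, the other three carry antibodies that change each round.
Turning the resulting pile of raw image tiles into biology requires a
computational chain — illumination correction, background subtraction,
stitching, cross-cycle rigid registration, nuclear segmentation,
single-cell quantification, cycle quality control, phenotype clustering
and spatial statistics. `cycifer` implements that chain as a tested R
package, together with a synthetic multiplexed-tissue generator with exact
ground truth so every stage can be validated without any external data.

It is written for imaging scientists and computational biologists who want
a transparent, end-to-end reference implementation of the t-CyCIF analysis
chain, or a controlled sandbox for studying how its stages behave.

## What it computes

* **Synthetic specimen** (`generate_phantom()`, `render_cycles()`):
  hard-core packed nuclei in tumor/stroma regions, per-cluster lognormal
  marker expression, per-cycle rigid stage drift, vignetting, decaying
  autofluorescence, Poisson + read noise, and spatially biased cell
  dropout; 16-bit TIFF tiles plus a ground-truth manifest.
* **Image prep** (`estimate_shading()`, `subtract_background()`,
  `stitch_grid()`, `register_cycles()`, `assemble_stack()`): retrospective
  flat-field correction, rolling-ball background removal (50 px ball),
  cross-correlation grid stitching with least-squares reconciliation, and
  rigid registration of every cycle onto the cycle-1 nuclear image
  (`r = 0.61 lambda / NA` style nominal resolutions are available via
  `nominal_resolution()`).
* **Segmentation and quantification** (`binarize_nuclei()`,
  `split_nuclei()`, `expand_cytoplasm()`, `quantify()`): Otsu threshold,
  seeded watershed on the distance transform, centripetal cytoplasm
  expansion (3 px at 10X / 6 px at 40X), and per-cell mean/integrated
  intensities for nucleus, cytoplasm and whole cell in every
  (cycle, channel).
* **Cycle QC** (`integrity_curve()`, `match_nuclei()`,
  `inactivation_fold()`, `dynamic_range()`, `overlap_score()`): tissue
  integrity relative to cycle 1, bleaching folds,
  `DR = log10(P95 / P5)`, and min/max-envelope overlap scores with
  high / moderate / low concordance classes (0.8 and 0.6 thresholds).
* **Phenotyping** (`transform_intensities()`, `normalize_channels()`,
  `fit_emgm()`, `select_k()`, `embed_tsne()`): asinh or log transform,
  1st–99th percentile normalization, full-covariance Gaussian-mixture EM
  with k-means++ starts and 30 restarts, model selection with the NLL
  curve exposed, and an exact t-SNE embedding (perplexity 30).
* **Spatial analysis** (`field_entropy()`, `gate_positive()`,
  `assign_regions()`, `knn_density()`, `cooccurrence_map()`,
  `bootstrap_counts()`): normalized Shannon entropy
  `-sum(s_i^2 ln s_i^2)` over 1000-cell field samples, Otsu marker gating,
  aSMA-based tumor/stroma assignment, kNN (k = 4) density maps,
  region-normalized co-occurrence with fold enrichment, and 100-round
  bootstrapped counts.

`run_pipeline()` orchestrates all stages with per-stage seeds and MD5
provenance; the numbered scripts under `analysis/` run the same chain as a
narrative study and write their tables under `results/`.

## A worked example

```r
library(cycifer)

cfg <- run_config(list(paths = list(output = "demo_run")))
run_pipeline(cfg)

read.csv("demo_run/integrity.csv")
#>   cycle count normalized retained
#> 1     1   500      1.000    1.000
#> 2     2   491      0.982    0.980
#> 3     3   482      0.964    0.962

jsonlite::read_json("demo_run/transforms.json", simplifyVector = TRUE)
#>   cycle        dx        dy        theta
#> 1     1  0.000000  0.000000  0.000000000
#> 2     2  3.985346 -2.992895  0.001783984
#> 3     3 -2.515657  1.507272 -0.002888124
```

The run simulated 500 cells with a 15% dropout schedule and stage drifts
of (4, −3, +0.1°) and (−2.5, 1.5, −0.15°). The integrity curve shows the
per-cycle nucleus count relative to cycle 1 falling as cells detach
(0.964 by cycle 3), and the registration recovered the generating drifts
to ~0.015 px and ~0.02° (0.001784 rad ≈ 0.102°). The cell table
(`demo_run/celltable.csv`) carries per-cell intensities for all cycles and
channels plus the fitted phenotype cluster (model selection chose k = 4:
the three simulated expression programs are recovered nearly one-to-one,
with a fourth small cluster collecting boundary cells) and the
aSMA-derived tumor/stroma label.

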