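---
title: "Methods: spatial leading-edge analysis with edgeniche"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spatial leading-edge analysis with edgeniche}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(edgeniche)
```

# Overview

`edgeniche` quantifies how gene expression and cell populations organize
around the *leading edge* of tumor regions in spatial transcriptomics
(ST) sections: the outer rim where tumor tissue abuts non-tumor tissue,
assigned distance 0 in every analysis. The package covers the full chain:

1. a synthetic-section generator with known ground truth,
2. readers/writers for Visium-like on-disk layouts,
3. lattice and raster geometry (neighbor graphs, tumor regions,
   edge-distance fields, shell density profiles),
4. niche calling and gene-set scoring,
5. enrichment statistics (permutation tests, odds ratios, BH control),
6. a file-based staged pipeline with a command-line wrapper.

This vignette documents the model and every numerical choice. All sizes
are micrometers unless stated.

# Synthetic sections

## Spot lattice

`generate_spot_grid()` builds a hexagonal (default) or square lattice.
Hex rows are offset by half a pitch and spaced `pitch * sqrt(3)/2`
apart; the first center sits half a pitch from the origin. Defaults
follow common ST platforms: 100 µm pitch, 50 µm spot diameter, a
3000 × 3000 µm section (1050 spots). The lattice is deterministic given
the configuration; the seed only drives counts and cells.

## Compartments

`assign_compartments()` paints five compartments: a tumor disc
(default radius 800 µm) split into concentric zones T1 (center) … T5
(rim) by `zone_edges_um`; surrounding `normal_gland` mucosa; and
concentric outer bands of `submucosa`, `muscularis` and a
`lymphoid_follicle` pocket. A guard rejects configurations whose disc
does not fit the section.

## Counts

Counts are negative binomial: `mu = base_mean(compartment, gene) * f(d)`
with dispersion `k` (`var = mu + mu^2/k`, default `k = 2`), where `d`
is the spot's distance to the region edge and

* `edge_high` genes: `f = 1 + A * exp(-d / tau)` (defaults `A = 4`,
  `tau = 150`) — e.g. CD44, Ptn, fibroblast and neutrophil markers;
* `center_high` genes: `f = 1 + A * exp(-(R - d) / tau)` with `R` the
  maximum in-tumor distance — e.g. Lgr5;
* all other genes are flat.

The default panel has 20 genes: five stemness markers (Alcam, Aldh2,
CD44, Lgr5, Prom1), Ptn, fibroblast (Col1a1, Il11, Pdgfrb, Acta2) and
neutrophil (Ly6g, Cd101) markers, compartment markers and housekeeping
genes.

## Cells

Single cells are an inhomogeneous Poisson process simulated by thinning
on the rasterized tumor mask, with intensity
`lambda(d) = lambda0 + lambda1 * exp(-d / tau)` cells/mm². Defaults:
CD44+ and CD44+PTN+ decay from the edge (`20 + 180 * exp(-d/100)`);
PTN+ is flat at 100 /mm², i.e. carries no planted spatial pattern.
`simulate_region_cells()` exposes the per-region primitive so cell
clouds can be planted on arbitrary masks (the test fixtures use long
rectangular strips).

## Reproducibility

Sub-streams are derived as `child_seed(seed, offset) = (seed + offset)
mod (2^31 - 1)`: counts use offset 1, cells offset 2, the pipeline's
enrichment stage offsets 10 and 11. Identical configurations reproduce
byte-identical outputs.

# Geometry

## Neighbor graph and regions

`build_adjacency()` links spots closer than `1.05 * pitch` (chunked
pairwise scan; an O(n²) oracle checks it in the tests). Interior degree
is 6 on hex and 4 on square lattices. `extract_tumor_regions()` takes
connected components of the tumor-spot subgraph (igraph), drops
components below `min_spots` (default 10) with a message, and marks
*boundary spots*: tumor spots with a missing or non-tumor lattice
neighbor.

## Two distance fields

* **Spot field** (`spot_edge_distance()`): Euclidean distance from each
  tumor spot center to the nearest boundary-spot center. Exact, no
  raster involved; boundary spots have distance 0.
* **Cell field** (`cell_edge_distance()`): regions are rasterized at
  10 µm pixels (Voronoi assignment of pixels to the nearest member
  spot, capped at 0.75 pitch, padded by one pitch of background), and
  the Euclidean distance transform (EBImage) is computed after forcing
  boundary pixels — mask pixels with a 4-neighbor outside — to 0, so
  the tumor boundary is exactly 0 µm. Cells outside the mask are
  excluded with a message. Rasters coarser than half a pitch are
  rejected. The EDT agrees with a brute-force boundary-pixel scan to
  within half a pixel diagonal; 10 µm pixels therefore bound distance
  errors by ~7 µm, small against the 50 µm bins.

## Shell profiles

`shell_profile()` bins cells into half-open 50 µm distance shells from
0. Densities divide shell counts by shell *areas* computed from the
pixel-level EDT of the same mask, so counts and areas always refer to
identical geometry. Classes default to *exclusive* semantics
(`CD44+` means CD44+PTN−); `superset = TRUE` counts every
marker-positive cell. `pool_profiles()` sums counts and areas across
regions before re-deriving densities — pooling data, not averaging
ratios.

# Niches and scores

`call_marker_niches()` ranks spots by a marker (descending, ties broken
by barcode) and takes the top `ceiling(q * N)` with `q = 0.10` by
default; scope is all spots or tumor-only. The call is rank-based and
hence invariant to monotone transforms and normalization.
`overlap_summary()` reports exact Venn regions and Jaccard matrices;
`niche_composition()` cross-tabulates members against tumor zones.

`auc_score()` is a recovery-curve score: genes ranked per spot
(descending, ties by gene id), window `n_top = floor(top_frac * G)`,
score = area under the cumulative signature-hit curve normalized by its
maximum. `module_score()` is a background-corrected mean: log1p CP10k
normalization, genes binned into 25 mean-expression bins, 50 control
genes drawn per signature gene from its bin (with replacement plus a
warning when a bin is small; a one-gene bin makes the gene its own
control, score 0), score = mean(signature) − mean(controls).
`population_signature_map()` chains scoring and top-quantile calling to
place cell-population signatures (built-in iCAF, myCAF, TAN sets) on
the section.

# Statistics

* `odds_ratio()`: closed-form OR with the Haldane–Anscombe 0.5
  correction when any cell is zero, Woolf (log-normal) 95% CI, Fisher's
  exact p on the uncorrected table; `bh_adjust()` applies
  Benjamini–Hochberg.
* `edge_enrichment_test()`: observed mean edge distance of a spot set
  versus resampled same-size subsets of the field;
  `p = (1 + #extreme) / (1 + n_perm)`.
* `density_trend_test()`: Spearman ρ of shell midpoints against
  densities; the null redistributes the total cell count over shells
  with probability proportional to shell area (a multinomial — exactly
  binned complete spatial randomness), so the test needs only the
  profile. At least 4 bins are required. Note the statistic is
  discrete: with few bins the permutation p is conservative, which is
  why calibration fixtures in the test-suite use 14 bins.
* `proximity_test()`: mean nearest-neighbor distance from set A to set
  B versus resampled A within a scope.

All permutation tests take mandatory seeds and are deterministic.

# Pipeline

`run_stage(stage, cfg)` executes `simulate`, `call-niches`,
`map-populations`, `edge-distance`, `profile`, `enrich`, `report` (or
`all`) against a YAML configuration validated by `run_config()`
(unknown keys are rejected). Stages communicate only through files in
the run directory, refuse to run before their upstream files exist, and
append provenance to `run_manifest.json`. `inst/cli/edgeniche` is a
thin Rscript wrapper over `en_cli()`.

# Design notes and limitations

* **Strip fixtures.** Gradient-recovery tests plant cells on long
  rectangular strips (~5000 × 700 µm) rather than discs: disc shells
  near the center have vanishing area, so binned Spearman trends on
  discs are underpowered regardless of implementation quality, while
  strips have near-constant shell areas. Fixture sizes were frozen
  after a power analysis on seeds disjoint from the test seeds.
* The generator is a caricature: independent NB genes, sharp
  compartment borders, isotropic gradients. It is designed for testable
  ground truth, not biological realism.
* Spot and cell fields use different boundary references (spot centers
  vs mask pixels); they agree to within about half a pitch, which the
  translation-invariance and oracle tests bound.
* Permutation p-values are lower-bounded by `1/(1 + n_perm)`; choose
  `n_perm` to match the smallest p you need to resolve.
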