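# edgeniche

Spatial leading-edge analysis of tumor transcriptomics.

## What this package is about

In colorectal tumors, cancer-stem-cell (CSC) marker expression is not
uniform: niches defined by markers such as CD44 concentrate along the
tumor's *leading edge* — the outer rim where tumor abuts non-tumor
tissue — while markers such as Lgr5 sit toward the center. The same
edge-ward organization shows up in single-cell densities of
marker-positive cells and in the placement of stromal populations
(inflammatory fibroblasts, tumor-associated neutrophils). `edgeniche`
implements the quantitative machinery behind this kind of analysis for
spot-based spatial transcriptomics (ST) plus segmented single-cell
point sets:

- **Geometry.** Tumor regions are connected components of the
  tumor-spot lattice graph. Boundary spots are tumor spots with a
  missing or non-tumor neighbor. Each tumor spot gets a distance
  `d(s) = min over boundary spots b of ||s - b||` (exact, lattice
  based); each cell gets a distance from the Euclidean distance
  transform of the rasterized region mask with the boundary fixed at
  0 µm.
- **Niches.** The top `ceiling(q N)` spots by a marker (default
  `q = 0.10`) form that marker's niche; calls are rank-based and
  tie-stable. Venn-style exact-region overlaps and per-zone composition
  summarize families of niches.
- **Scores.** Gene-set activity per spot via a rank-recovery AUC score
  and a background-corrected module score (expression-bin-matched
  control genes).
- **Shell profiles.** Cell densities in half-open 50 µm distance
  shells, `density = count / shell area`, with areas derived from the
  same mask pixels; profiles pool across regions by summing counts and
  areas.
- **Statistics.** Permutation tests for edge enrichment
  (`p = (1 + #extreme)/(1 + n_perm)`), center-to-edge density trends
  (Spearman ρ against a binned-CSR multinomial null), and set-to-set
  proximity; odds ratios with Haldane–Anscombe correction, Woolf CIs,
  Fisher p-values and Benjamini–Hochberg control.
- **Synthetic data.** A seeded generator draws hex/square lattices,
  five tissue compartments with concentric tumor zones, negative
  binomial counts with edge- or center-weighted gradients
  (`mu = base * (1 + A exp(-d/tau))`), and inhomogeneous Poisson cell
  clouds (`lambda(d) = lambda0 + lambda1 exp(-d/tau)` per mm²) — so
  every stage can be validated against known ground truth.
- **Pipeline.** A staged, file-based pipeline (`simulate` →
  `call-niches` → `map-populations` → `edge-distance` → `profile` →
  `enrich` → `report`) driven by a YAML config, with a CLI wrapper in
  `inst/cli/edgeniche` and a provenance manifest per run.

## Worked example

Simulate a default section (1050 spots, 20 genes, seeded cells), locate
the tumor region and ask where the CD44 and Lgr5 niches sit:

```r
library(edgeniche)

cfg <- synthetic_config(seed = 7)
sec <- simulate_section(cfg)          # grid + compartments + counts + cells
dim(sec$counts)
#> [1]   20 1050

adj     <- build_adjacency(sec$grid)
regions <- extract_tumor_regions(sec$compartments, adj, sec$grid)
length(regions)
#> [1] 1

fld <- spot_edge_distance(regions[[1]], sec$grid)
summary(fld$distance_um)
#>    Min. 1st Qu.  Median    Mean 3rd Qu.    Max.
#>     0.0   100.0   173.2   205.6   346.4   692.8

cd44 <- call_marker_niches(sec$counts, sec$compartments, "CD44",
                           q = 0.10, scope = "tumor_only")
lgr5 <- call_marker_niches(sec$counts, sec$compartments, "Lgr5",
                           q = 0.10, scope = "tumor_only")
mean(fld$distance_um[match(cd44$members, fld$subject_id)])
#> [1] 36.38355
mean(fld$distance_um[match(lgr5$members, fld$subject_id)])
#> [1] 300.9646
```

The CD44 niche hugs the boundary (36 µm mean distance versus 301 µm for
Lgr5). A permutation test makes that quantitative:

```r
edge_enrichment_test(cd44$members, fld, n_perm = 999, seed = 7)[
  c("observed_stat", "null_mean", "p_value")]
#> $observed_stat
#> [1] 36.38355
#> $null_mean
#> [1] 206.1402
#> $p_value
#> [1] 0.001
```

Cell-level density gradients use the raster distance field and 50 µm
shells:

```r
cells <- cell_edge_distance(regions[[1]], sec$cells)
prof  <- shell_profile(cells, regions[[1]], sec$cells)
subset(prof, class == "CD44+PTN+",
       select = c(bin_lo, bin_hi, count, area_mm2, density_per_mm2))
#>    bin_lo bin_hi count area_mm2 density_per_mm2
#> 31      0     50    42   0.3136       133.92857
#> 32     50    100    31   0.2622       118.23036
#> 33    100    150    12   0.2182        54.99542
#> 34    150    200    12   0.1950        61.53846
#> 35    200    250    12   0.1752        68.49315
#> 36    250    300     7   0.1604        43.64090
#> 37    300    350     6   0.1432        41.89944
#> 38    350    400     4   0.1244        32.15434
#> 39    400    450     5   0.1080        46.29630
#> 40    450    500     1   0.0910        10.98901
#> 41    500    550     1   0.0750        13.33333
#> 42    550    600     2   0.0586        34.12969
#> 43    600    650     0   0.0422         0.00000
#> 44    650    700     2   0.0256        78.12500
#> 45    700    750     0   0.0078        0.00000

tr <- density_trend_test(prof, "CD44+PTN+", n_perm = 999, seed = 7)
c(rho = tr$spearman_rho, p = tr$test$p_value)
#>        rho          p
#> -0.6970512  0.0100000
```

A single disc-shaped region gives a noisy trend (inner shells have tiny
areas); pooling profiles across regions with `pool_profiles()` is how
the test gains power in practice.

The same chain runs end-to-end from a YAML config:

```r
run_stage("all", run_config("run.yaml"))
```

or from the shell via `inst/cli/edgeniche all --config run.yaml`,
leaving `niches.tsv`, `profile.csv`, `stats.json`, `report.txt` and a
`run_manifest.json` in the run directory.

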