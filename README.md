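# imcniche

Spatial single-cell analysis of multiplexed tissue images in R.

Imaging mass cytometry (IMC) and related multiplexed imaging technologies
produce one intensity channel per metal-tagged antibody at ~1 µm
resolution. Given such channel stacks plus a cell segmentation label mask,
`imcniche` runs the full downstream spatial analysis that studies of the
brain tumour microenvironment (glioblastoma and brain metastases) rely on:

1. **Marker mask curation** — per-channel binary foreground masks via
   3×3 median filtering, 1-D k-means quantization into 6 intensity
   levels, bright-level selection, small-blob removal and optional
   adaptive local-mean refinement.
2. **Pixel-majority lineage assignment** — each pixel carries a binary
   presence vector E(p) over the lineage-marker masks; summing over a
   cell's pixels gives its majority vector M, and the maximal entry
   (ties broken by a rank-priority hierarchy) assigns the lineage.
   Cells with an all-zero vote are `Undefined` but stay in every spatial
   analysis. Subphenotypes (microglia vs MDM by P2Y12, M1-like vs
   M2-like by CD163, MPO⁺) follow mask-positivity calls.
3. **Cell–cell interaction tests** — cells within a 6 µm centroid radius
   interact; for each ordered type pair (A, B) the mean number of
   B-neighbours per A-cell is compared against a null built by shuffling
   phenotype labels over the image (1,000 permutations), calling
   *interact* / *avoid* at P < 0.01, read row-to-column.
4. **Cellular neighbourhoods (CNs)** — each cell's window is the
   frequency vector of its N nearest cells' types; windows pooled across
   images are clustered with mini-batch k-means (batch 100, seed 0) into
   K CNs; per-image CN prevalence is normalized to 100 % and cohorts are
   stratified at prevalence z ≥ 0 vs z < 0 (or by median).
5. **Hybrid phenotype clustering** — t-SNE embedding, DBSCAN
   (eps 3, minPts 30) to isolate density clusters, spectral re-clustering
   of the dominant cluster on a 1-in-10 subsample, and a 5-NN classifier
   to label every cell.
6. **Cohort statistics and survival** — cell frequencies/densities,
   Shapiro–Wilk-driven test selection (t / Mann–Whitney / ANOVA + Tukey),
   Fisher's exact test, Kaplan–Meier curves and log-rank tests with
   per-patient averaging of duplicate cores.
7. **Synthetic tissue generation** — a marked point process (CSR,
   Thomas-cluster attraction, hard-core avoidance, planted neighbourhood
   regions) rendered into channel stacks with lognormal signal over
   exponential background, plus survival times with a planted log-linear
   hazard — ground truth for every stage above.

## Worked example

Simulate one core, curate masks, phenotype cells and test spatial
interactions:

```r
library(imcniche)

cfg <- sim_config(width = 300, height = 300, n_cells = 250,
                  proportions = c(Tumour = 0.4, Macrophage = 0.3,
                                  Endothelial = 0.2, Undefined = 0.1))
im  <- generate_image(cfg, seed = 1, image_id = "core1")
sp  <- sim_panel(cfg)

masks <- curate_masks(im$stack, sp$panel, seed = 7)
cells <- phenotype_cells(im$seg, im$stack, masks, sp$hierarchy)
mean(cells$lineage == im$cells$lineage)
#> [1] 0.996

g   <- build_graph(cells$centroid_x_um, cells$centroid_y_um, radius_um = 6)
res <- interaction_test(g, cells$lineage, n_perm = 1000, seed = 3)
head(res[, c("type_a", "type_b", "observed", "p_interact", "call")], 3)
#>        type_a      type_b observed p_interact call
#> 1 Endothelial Endothelial        0          1   ns
#> 2  Macrophage Endothelial        0          1   ns
#> 3      Tumour Endothelial        0          1   ns
```

99.6 % of cells recover their planted lineage through the full
mask-curation and majority-vote pipeline. The interaction calls are all
`ns` here because rendered images pack cells as non-overlapping discs
(centroids ≥ 9 µm apart with the default radius), so the 6 µm graph is
empty — interaction analyses operate on the point-process stage, where
planted attraction and avoidance are detected (see the vignette):

```r
att <- sim_config(width = 1000, height = 1000, n_cells = 500,
                  proportions = c(A = 0.3, B = 0.3, C = 0.4),
                  interactions = list(list(pair = c("A", "B"),
                                           mode = "attraction", scale_um = 4)))
ca <- generate_cells(att, seed = 5)
ga <- build_graph(ca$centroid_x_um, ca$centroid_y_um, 6)
ra <- interaction_test(ga, ca$lineage, n_perm = 1000, seed = 5)
ra[ra$type_a == "A" & ra$type_b == "B",
   c("observed", "null_mean", "p_interact", "call")]
#>    observed null_mean  p_interact     call
#> 4 0.6083916 0.1287203 0.000999001 interact
```

Neighbourhood discovery and survival stratification follow the same
pattern: `neighbour_windows()` → `fit_cn()` → `cn_prevalence()` →
`stratify_by_cn()` → `km_logrank()`.

## Documentation

The methods vignette (`vignettes/imcniche-methods.Rmd`) describes the
models, parameter conventions, numerical choices and the limits of what
the synthetic benchmarks demonstrate.
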