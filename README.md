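# tmescope

Dissecting the tumor microenvironment (TME) from single-cell RNA-seq UMI
counts: who talks to whom through which immune-checkpoint axes, which
copy-number clones a tumor contains, and how immune composition varies
across patients. The package targets analysts working with multi-patient
cohorts of droplet single-cell data — the motivating setting is
hepatocellular carcinoma, where malignant cells are patient-private while
immune and stromal states are shared — and packages the bespoke statistics
such studies rely on as tested, reusable, tidyverse-styled functions.

## What it computes

**Checkpoint interaction score with a permutation null.** For a
ligand–receptor axis between a sender type *s* (the ligand side, e.g. tumor
cells or macrophages) and a receiver type *r* (the receptor side, e.g. T or
NK cells), on log-normalized expression:

```
S = mean(ligand | cells of type s) × mean(receptor | cells of type r)
```

Significance is empirical: shuffle the cell-type label vector B times
(keeping every type's cell count fixed; B = 1000 by default) and report

```
p = #( S_perm > S_obs ) / B
```

`checkpoint_panel()` evaluates a whole axis × sender × receiver grid against
one shared, seeded permutation ensemble; `permutation_p()` handles a single
axis, including exhaustive enumeration on small two-group problems.

**Pan-ligand–receptor interactome.** `interactome()` scores every curated
pair over all ordered cell-type pairs, tests each pair's median score
against zero with a one-sided one-sample Wilcoxon signed-rank test, corrects
across pairs with Storey q-values (`storey_qvalue()`, π₀ by the smoother
method), and calls a pair significant when median score > 0.5 and q < 0.05.

**Expression-inferred CNV.** `relative_expression()` centers log expression
on a diploid reference population and clamps at ±3;
`cnv_moving_average()` smooths along chromosome-sorted genes with a
100-gene sliding window per chromosome; `center_on_reference()` zeroes the
reference; `cluster_cnv_groups()` cuts an average-linkage dendrogram into
CNV groups (Newick export via `as_newick()`).

**Stratification and composition.** `lcsc_groups()` clusters tumor cells on
the nine-gene liver cancer-stem-cell panel (EPCAM, KRT19, ALDH1A1, CD13,
CD24, CD44, CD47, CD90, CD133; protein→transcript aliases bundled);
`composition()` tabulates per-sample cell-type proportions and
`proportion_correlation()` tests two types' proportions across samples with
a two-sided Pearson correlation.

**Ground-truthed simulation.** `simulate_tme()` draws negative-binomial UMI
counts with planted cell types, checkpoint axes, patient-private CNV
segments and multiplets; `simulate_barnyard()` plants a two-species mixing
experiment for the multiplet-rate estimator (`estimate_multiplet_rate()`).
Everything is seeded and byte-reproducible.

`run_pipeline(demo_config())` chains simulate → qc → annotate → cnv →
checkpoint → interactome → markers → correlate, writing TSV outputs plus a
manifest of parameters, sub-seeds and file hashes. A thin command-line
wrapper lives at `inst/scripts/tmescope.R`.

## Worked example

```r
library(tmescope)

sim  <- simulate_tme(sim_config(seed = 1))
sim
#> tme_sim: 1368 cells x 1250 genes, 8 patients, 8 doublets

expr <- normalize_counts(sim$counts, scale = sim_scale_factor(ncol(sim$counts)))
ann  <- assign_cell_types(expr, sim$markers)
mean(ann$cell_type == sim$truth$cell_type[match(ann$barcode, sim$truth$barcode)])
#> [1] 0.994152

pairs <- read_lr_pairs(system.file("extdata", "checkpoint_pairs.tsv",
                                   package = "tmescope"))
cp <- checkpoint_panel(expr, ann, pairs,
                       sender_types   = c("Tumor", "TAM"),
                       receiver_types = c("CD8T", "CD4T", "Treg", "NK"),
                       B = 1000, seed = 1)
dplyr::arrange(dplyr::filter(cp, !is.na(p)), p, dplyr::desc(score)) |> head(5)
#> # A tibble: 5 × 9
#>   axis          ligand  receptor sender receiver score     p n_perm mode
#>   <chr>         <chr>   <chr>    <chr>  <chr>    <dbl> <dbl>  <dbl> <chr>
#> 1 NECTIN2-TIGIT NECTIN2 TIGIT    Tumor  CD8T     1.68      0   1000 strict
#> 2 NECTIN2-TIGIT NECTIN2 TIGIT    TAM    CD8T     0.458     0   1000 strict
#> 3 NECTIN2-TIGIT NECTIN2 TIGIT    Tumor  NK       0.457     0   1000 strict
#> 4 NECTIN2-TIGIT NECTIN2 TIGIT    Tumor  Treg     0.408     0   1000 strict
#> 5 NECTIN2-TIGIT NECTIN2 TIGIT    Tumor  CD4T     0.389     0   1000 strict
```

The simulation planted an 8-fold NECTIN2–TIGIT program on tumor cells and
CD8 T cells; that axis tops the Tumor→CD8T direction with score 1.68 and an
empirical P of 0 at B = 1000 (i.e. no permuted score exceeded it), while
the annotation step recovered 99.4% of planted cell identities. The
multiplet-rate estimator applied to a simulated equal-mix barnyard run
(planted rate 0.6%) reads:

```r
by <- simulate_barnyard(n_a = 5000, n_b = 5000, doublet_rate = 0.006, seed = 1)
estimate_multiplet_rate(by$counts)
#> # A tibble: 1 × 4
#>      rate cross_rate n_cross n_cells
#>     <dbl>      <dbl>   <int>   <int>
#> 1 0.00537    0.00268      27   10060
```

— 27 of 10,060 barcodes are cross-species impure; doubling the cross rate
(same-species doublets are invisible under equal mixing) estimates a 0.54%
total multiplet rate.

The methods vignette (`vignettes/tmescope-methods.Rmd`) documents the
models, parameter defaults, simulator assumptions and design decisions.

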