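---
title: "Dissecting the tumor microenvironment with tmescope: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dissecting the tumor microenvironment with tmescope}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tmescope)
library(dplyr)
```

tmescope re-implements, as reusable and tested functions, the bespoke
computations used to dissect a multi-patient hepatocellular-carcinoma (HCC)
tumor microenvironment from droplet single-cell RNA-seq: quality control and
barnyard multiplet estimation, marker-panel cell typing, permutation-tested
immune-checkpoint interaction scoring, pan-ligand–receptor interactome
scoring with Wilcoxon/Storey aggregation, expression-inferred copy-number
(CNV) profiling, stem-cell-marker tumor stratification, and immune
composition correlation. A seeded simulator plants ground truth for every
stage, so each claim the package makes about recovery or calibration is a
testable statement about planted structure.

This vignette explains the models and their assumptions, the tunable
parameters, what the simulator does and does not emulate, and the numerical
choices made where the underlying procedures are conventionally left
unstated.

## The interaction score and its permutation null

For a ligand–receptor axis (for example NECTIN2 on antigen-presenting cells
binding TIGIT on T/NK cells), the interaction level between a sender type
$s$ and receiver type $r$ is

$$S = \overline{x}_{\mathrm{lig},\,s} \times \overline{x}_{\mathrm{rec},\,r},$$

the product of the mean log-normalized ligand expression over sender cells
and the mean receptor expression over receiver cells. $S$ is bilinear:
scaling ligand expression by $c$ scales $S$ by $c$. It has no absolute
units; it is interpreted relative to a permutation null and, for the
interactome analysis, against a conventional threshold (below).

Significance comes from shuffling the cell-type label vector while keeping
every type's cell count fixed — the null hypothesis is that expression is
exchangeable across cell identities. With $B$ permutations (default 1000,
`checkpoint_panel()`), the empirical P is

$$p = \#\{S^{(b)} > S_{\mathrm{obs}}\} / B.$$

Two deliberate choices here:

* **Permutation scope.** By default the *entire* label vector over all
  annotated cells is shuffled ("global" mode), because keeping the original
  cell-type ratio of the full annotation is the natural reading of
  label-permutation with fixed group sizes; a faster two-group mode
  (`scope = "pair"`) conditions on the union of the two involved types.
* **Tie handling.** The strict `>` rule returns $p = 0$ when all permuted
  scores tie the observed score (for instance on constant expression). This
  literal rule is the default and is what the acceptance checks exercise; a
  `plus_one` mode, $p = (\#\{S^{(b)} \ge S\} + 1)/(B + 1)$, is provided and
  recommended when a never-zero, never-anti-conservative p-value is needed.
  The mode used is recorded in every result row.

`checkpoint_panel()` draws one seeded set of $B$ permutations and shares it
across all (axis, sender, receiver) triples, so every axis is measured
against the same null ensemble; cells are processed in sorted-barcode order,
making seeded results exactly invariant to input row order. For tiny
two-group problems `permutation_p(exhaustive = TRUE)` enumerates every
distinct label assignment instead of sampling.

## Interactome aggregation: Wilcoxon + Storey q-values

For a curated pair table (a small illustrative checkpoint table ships in
`inst/extdata/checkpoint_pairs.tsv`; any user table with `ligand` and
`receptor` columns is accepted), `interactome()` scores each pair over all
ordered sender–receiver type pairs with sender ≠ receiver, then asks whether
the pair interacts *somewhere* in the type space: a one-sided one-sample
Wilcoxon signed-rank test of whether the median score across type pairs
exceeds zero (zeros dropped per the standard signed-rank convention; exact
null for $n \le 25$ without ties, normal approximation with continuity
correction above). Multiplicity across pairs is controlled with Storey
q-values, and a pair is called significant when its **median** score exceeds
0.5 and $q < 0.05$.

Choices worth stating:

* **Which aggregate the 0.5 threshold applies to.** The threshold is applied
  to the median per-pair score across cell-type pairs — the same quantity
  whose median the Wilcoxon tests, so the two significance conditions speak
  about one number. Both thresholds are arguments.
* **π₀ estimation.** `storey_qvalue()` estimates the null proportion with
  the smoother method: $\hat\pi_0(\lambda) = \#\{p > \lambda\}/(m(1 -
  \lambda))$ on the grid λ = 0.05…0.95 (step 0.05), fit with a natural
  cubic spline (3 df) and read off at the largest λ, clamped to (0, 1].
  Fixing `pi0 = 1` recovers Benjamini–Hochberg adjusted p-values exactly,
  which is how the implementation is cross-checked.
* **Single-gene pairs only.** Multi-subunit complexes are out of scope; a
  pair is one ligand gene and one receptor gene.

Because interaction scores over non-negative expression are almost surely
positive wherever both genes are expressed, the Wilcoxon p-value is small
for most expressed pairs; the score threshold, not the q-value, is what
separates biologically substantial interactions from background. This
mirrors how the thresholds behave on real data.

## Expression-inferred CNV

Copy number is proxied from expression in three steps:

1. `relative_expression()`: per gene, subtract the mean log-normalized
   expression over a diploid **reference population** (normal hepatocytes in
   the HCC setting; any user-declared reference serves) and clamp to
   ±`cap` (default 3) so single extreme genes cannot dominate windows.
2. `cnv_moving_average()`: sort genes by chromosome position and average
   over sliding windows of `window` consecutive genes (default 100, the
   standard smoothing width for this class of method) at stride `step`
   (default 1, maximally overlapping). Chromosomes shorter than one window
   contribute a single truncated window flagged in the window map rather
   than disappearing silently; genes without positions are excluded with a
   logged count.
3. `center_on_reference()`: subtract the reference-cell mean per window, so
   the reference population reads exactly zero and tumor scores read as
   deviations from diploid.

`cluster_cnv_groups()` then groups tumor cells by agglomerative hierarchical
clustering (Euclidean distance, average linkage — the linkage is a choice,
not a given) on their window scores, cut at a user-supplied `k` or height;
the dendrogram exports to Newick. The number of CNV groups in any real
cohort is data-specific, so `k` is never defaulted; clustering can be run
globally or within cases by subsetting the profile.

**A known confound, by design visible in the simulator:** windows that
contain genes whose expression differs between tumor and reference for
*regulatory* reasons — identity programs, marker genes — deviate from zero
without any copy-number change. The simulator places its planted identity
programs on the last simulated chromosome, keeps default lesions off it, and
the false-positive test evaluates the CNV-interpretable chromosomes; on real
data the analogous practice is excluding or down-weighting known
differential loci when interpreting expression-CNV maps.

## Preprocessing

* **QC**: cells failing `min_genes` (default 200) or `max_mito` (default
  0.2) are removed, then genes seen in fewer than `min_cells_per_gene`
  (default 3) retained cells. These defaults are package choices in the
  range conventional for droplet data — per-case thresholds in any given
  study are tuning decisions. The output is a pure submatrix: no value is
  altered. Mitochondrial genes are recognized by the human `MT-` prefix or
  an explicit list (simulations use explicit lists).
* **Multiplet rate**: in a two-species barnyard mix, a barcode whose
  majority-species purity falls below 0.9 (configurable) is a cross-species
  multiplet; under equal mixing half of multiplets are same-species and
  invisible, so the reported rate is twice the cross-species rate.
* **Normalization**: counts-per-10,000 followed by `log1p` — the convention
  of the standard single-cell toolkits, since the procedure itself is
  usually named but not specified.
* **HVG selection**: variance-to-mean dispersion standardized within 20
  equal-count mean bins, top `n_top`, ties broken by gene symbol.
* **Cell typing**: the per-type score is the unweighted mean normalized
  expression of that type's markers; the argmax wins, ties resolve by the
  declared type order and are flagged low-confidence, and the margin to the
  runner-up is reported. Unweighted means with no background correction are
  the simplest scheme that meets the recovery property below; the panel is
  an argument, so weighted or background-corrected scoring can replace it.

## Tumor heterogeneity and composition

`lcsc_groups()` stratifies tumor cells by unsupervised hierarchical
clustering (Euclidean, average linkage) on the nine-marker liver
cancer-stem-cell panel — EPCAM, KRT19, ALDH1A1, CD13, CD24, CD44, CD47,
CD90, CD133 — using continuous normalized expression (binarization is a
defensible alternative; continuous values preserve gradations and need no
extra threshold). Protein names map to transcript symbols (CD13→ANPEP,
CD90→THY1, CD133→PROM1) via a bundled alias table. The per-(sample × group)
contingency table mirrors the per-case tabulation such studies report.

`composition()` computes per-sample cell-type proportions over a declared
type set (summing to one per sample), with optional subset-within-parent
proportions (for example CD8 T within all T cells).
`proportion_correlation()` is a two-sided Pearson correlation across
samples, p from the t distribution on $n-2$ df; a p-value underflowing
double precision is reported as the smallest positive double rather than 0.
Correlation is computed on raw proportions to match the conventional
analysis; note the compositional caveat — with only two types the
proportions are complementary and $r = -1$ by construction, which the
package warns about rather than reporting as biology.

## The simulator: what it emulates, and what it does not

`simulate_tme()` draws gamma–Poisson (negative binomial) UMI counts:
gene-level base means are log-normal(log 0.5, 1.2) — about 1,300 UMIs per
cell over the default 1,250 genes, a realistic desk-scale stand-in for
droplet data — with NB size 2 and a per-cell library factor log-normal(0,
0.3) so normalization is a non-trivial step. No zero-inflation term is
added: dropout emerges from low means, as in the accepted UMI noise model.

Planted structure, all recorded as ground truth:

* **Patients and types**: 8 patients × 10 cell types by default (tumor,
  CD8/CD4/regulatory T, NK, B, macrophage, endothelial, fibroblast,
  hepatocyte); per-patient compositions may be a matrix, and
  `tradeoff_composition()` builds the inverse macrophage/T-cell pattern with
  slope −1 on shares and 5% multiplicative noise.
* **Identity programs**: each type up-weights its markers `marker_fold`-fold
  (default 8; 10 markers/type — the order of magnitude of published marker
  tables). Marker and checkpoint genes get base mean 1 rather than a
  genome-tail draw, because canonical markers are by construction expressed
  genes.
* **Checkpoint axes**: ligand up-weighted in the sender type and receptor in
  the receiver type; `"*"` plants a broadly expressed axis for interactome
  power experiments.
* **CNV lesions**: contiguous gene ranges per chromosome scaling tumor-cell
  NB means by $2^{\mathrm{log2fc}}$; given as gene-index ranges because the
  analysis window width is an analysis parameter, not a property of the
  data. Chromosomes are contiguous 250-gene blocks at 10-kb spacing.
* **Multiplets**: extra barcodes summing two uniformly chosen cells at rate
  0.006 — the rate a well-run droplet experiment reports.
  `simulate_barnyard()` adds the two-species design with 0.5% Poisson
  ambient cross-contamination.

One scale subtlety: the counts-per-10,000 convention presumes a full
(~20,000-gene) transcriptome. Concentrating a cell's library into 1,250
simulated genes would inflate normalized magnitudes roughly 16-fold and
detach the interactome's absolute score threshold from its conventional
scale. Analyses of simulated data therefore normalize to
`sim_scale_factor(n_genes)` = 1e4 × n_genes / 20000, keeping magnitudes on
the real-data scale; `normalize_counts()` itself defaults to 1e4.

What the simulator does **not** emulate: batch effects (the motivating
setting found none to model), ambient RNA beyond the barnyard term,
cell-cycle or continuous differentiation structure, per-case cell-type
proportions of any particular cohort, and realistic gene–gene correlation.
Passing recovery tests on this generator therefore demonstrates that the
*statistics* behave as claimed under a faithful noise model — not that any
particular biological conclusion transfers to a given dataset.

## Problem sizes and runtime choices

The test and acceptance workloads are sized for a laptop-class single core:
default cohorts of ~1,400 cells × 1,250 genes; permutation panels at
B = 1000; calibration over 20 null cohorts × 100 pairs (2,000 p-values,
checking the fraction below 0.05 against its binomial interval); power
checks with planted folds of 8 (checkpoint, interactome blocks) and lesions
of |log2FC| ∈ {0.5, 1} spanning ≥ 3 windows; a 10,000-cell barnyard at the
0.6% multiplet rate. The demonstration pipeline (`run_pipeline()`,
`demo_config()`) runs end-to-end in seconds and is byte-reproducible under a
fixed seed: every stage draws from a sub-seed derived from the global seed
and the stage name, so adding a stage never shifts another stage's
randomness.

## Degenerate inputs and tie-breaks, collected

* Square count matrices cannot be orientation-auto-detected and require an
  explicit flag; silent transposition is never allowed.
* QC thresholds that would remove every cell raise an error instead of
  returning an empty object.
* An all-zero cell in `assign_cell_types()` ties every type and resolves to
  the first declared type, flagged low-confidence.
* HVG ranking breaks ties on gene symbol; requesting more genes than exist
  returns all with a warning.
* An all-zero interactome score vector yields Wilcoxon p = 1 (not an
  error); genes absent from the matrix score 0 with a warning.
* `cluster_cnv_groups()` rejects `k` above the cell count; duplicated cells
  co-cluster at height zero.
* Chromosomes shorter than the CNV window produce flagged truncated
  windows.

## Limitations

The interaction score treats types as homogeneous pools (no per-cell
communication inference, no spatial constraints) and single-gene pairs only.
Expression-CNV has no HMM segmentation or integer copy calling, and is
confounded at differentially regulated loci as discussed. The Storey
estimator is unstable for very few tests; with a handful of p-values, fixing
π₀ = 1 (BH) is the safer choice. Cluster counts (`k`) for CNV and LCSC
groupings are scientific choices the package deliberately refuses to make
for you.
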