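# Shared fixture builders for the suite. Everything is generated in code;
# no binary fixtures.

# A dense cell x gene matrix with sequential barcodes / gene symbols.
toy_matrix <- function(values, n_cells, n_genes,
                       barcodes = sprintf("C%02d", seq_len(n_cells)),
                       genes = sprintf("G%02d", seq_len(n_genes))) {
  m <- matrix(values, nrow = n_cells, ncol = n_genes,
              dimnames = list(barcodes, genes))
  Matrix::Matrix(m, sparse = TRUE)
}

toy_annotation <- function(counts, cell_type, sample = "S1") {
  tibble::tibble(barcode = rownames(counts), sample = sample,
                 cell_type = cell_type)
}

# Write an MTX triplet by hand (text), returning the three paths.
write_mtx_fixture <- function(dir, n_row, n_col, entries, barcodes, genes) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  mtx <- file.path(dir, "matrix.mtx")
  writeLines(c(
    "%%MatrixMarket matrix coordinate integer general",
    paste(n_row, n_col, nrow(entries)),
    apply(entries, 1L, paste, collapse = " ")
  ), mtx)
  bc <- file.path(dir, "barcodes.tsv")
  writeLines(barcodes, bc)
  ft <- file.path(dir, "features.tsv")
  writeLines(genes, ft)
  list(mtx = mtx, barcodes = bc, features = ft)
}

# Small default-structure simulation for integration-style tests.
small_sim_config <- function(seed = 1L, ...) {
  defaults <- list(
    seed = seed,
    n_patients = 2L,
    cells_per_type = c(Tumor = 30L, CD8T = 20L, TAM = 20L, Hepatocyte = 20L),
    n_genes = 300L,
    genes_per_chrom = 100L,
    doublet_rate = 0
  )
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

# Normalization scale for simulated data (partial transcriptome).
sim_expr <- function(sim) {
  normalize_counts(sim$counts, scale = sim_scale_factor(ncol(sim$counts)))
}

# Adjusted Rand Index (chance-corrected clustering agreement).
ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# Windows of a cnv_profile lying fully inside a (chrom, start_gene,
# end_gene) segment, with gene indices counted within the chromosome.
segment_windows <- function(profile, positions, chrom, start_gene, end_gene) {
  wm <- profile$window_map
  poschr <- positions[positions$chrom == chrom, ]
  poschr <- poschr[order(poschr$start), ]
  w <- which(wm$chrom == chrom)
  w[match(wm$start_gene[w], poschr$gene) >= start_gene &
      match(wm$end_gene[w], poschr$gene) <= end_gene]
}

# Fraction of in-segment (cell, window) entries whose sign matches the
# planted lesions of a simulation.
cnv_sign_recovery <- function(profile, sim) {
  truth <- sim$truth
  seg <- sim$cnv_segments
  hits <- unlist(lapply(seq_len(nrow(seg)), function(i) {
    wi <- segment_windows(profile, sim$gene_positions, seg$chrom[i],
                          seg$start_gene[i], seg$end_gene[i])
    cells <- intersect(
      truth$barcode[truth$patient == paste0("P", seg$patient[i]) &
                      truth$cell_type == "Tumor" & !truth$is_doublet],
      rownames(profile$scores)
    )
    sign(profile$scores[cells, wi, drop = FALSE]) == sign(seg$log2fc[i])
  }))
  mean(hits)
}
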