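#' Compute per-cell QC metrics
#'
#' Total counts, detected genes, and the fraction of counts from
#' mitochondrial genes. Mitochondrial genes are identified by the `MT-`
#' symbol prefix by default (human convention); pass an explicit gene vector
#' to override (simulations use explicit lists).
#'
#' @param counts Cell-by-gene count matrix.
#' @param mito A regular expression matched against gene symbols (default
#'   `"^MT-"`) or an explicit character vector of mitochondrial genes.
#' @return A tibble: `barcode`, `n_counts`, `n_genes`, `mito_frac`.
#' @export
compute_qc_metrics <- function(counts, mito = "^MT-") {
  mito_genes <- if (length(mito) == 1L && !mito %in% colnames(counts)) {
    grep(mito, colnames(counts), value = TRUE)
  } else {
    intersect(mito, colnames(counts))
  }
  totals <- Matrix::rowSums(counts)
  mito_counts <- if (length(mito_genes)) {
    Matrix::rowSums(counts[, mito_genes, drop = FALSE])
  } else {
    rep(0, nrow(counts))
  }
  tibble(
    barcode = rownames(counts),
    n_counts = as.numeric(totals),
    n_genes = as.numeric(Matrix::rowSums(counts > 0)),
    mito_frac = as.numeric(ifelse(totals > 0, mito_counts / totals, 0))
  )
}

#' Quality-control filtering of cells and genes
#'
#' Removes cells with fewer than `min_genes` detected genes or a
#' mitochondrial fraction above `max_mito`, then removes genes expressed in
#' fewer than `min_cells_per_gene` of the retained cells. The output is a
#' submatrix of the input: no value is modified. Removal counts are reported
#' in the `log` element and as a message.
#'
#' @param counts Cell-by-gene count matrix.
#' @param annotation Per-cell tibble with a `barcode` column covering all
#'   cells; `n_genes` / `mito_frac` are computed if absent (see `mito`).
#' @param min_genes,max_mito,min_cells_per_gene Thresholds; defaults 200,
#'   0.2 and 3.
#' @param mito Passed to [compute_qc_metrics()] when metrics are computed.
#' @return A list: `counts`, `annotation` (retained rows, metrics attached),
#'   `log` (one-row tibble of removal counts).
#' @export
qc_filter <- function(counts, annotation, min_genes = 200L, max_mito = 0.2,
                      min_cells_per_gene = 3L, mito = "^MT-") {
  if (min_genes < 0) abort_config("min_genes must be >= 0")
  if (max_mito < 0 || max_mito > 1) abort_config("max_mito must lie in [0, 1]")
  missing_bc <- setdiff(rownames(counts), annotation$barcode)
  if (length(missing_bc)) {
    abort_format(paste0("annotation does not cover ", length(missing_bc),
                        " barcode(s), e.g. ", missing_bc[[1]]))
  }
  annotation <- annotation[match(rownames(counts), annotation$barcode), ]
  if (!all(c("n_genes", "mito_frac") %in% names(annotation))) {
    qc <- compute_qc_metrics(counts, mito = mito)
    annotation <- left_join(
      annotation[, setdiff(names(annotation),
                           c("n_counts", "n_genes", "mito_frac"))],
      qc, by = "barcode"
    )
  }
  keep_cell <- annotation$n_genes >= min_genes & annotation$mito_frac <= max_mito
  if (!any(keep_cell)) {
    abort_config(paste0(
      "QC thresholds (min_genes = ", min_genes, ", max_mito = ", max_mito,
      ") remove all ", nrow(counts), " cells"
    ))
  }
  sub <- counts[keep_cell, , drop = FALSE]
  keep_gene <- Matrix::colSums(sub > 0) >= min_cells_per_gene
  log <- tibble(
    cells_in = nrow(counts), cells_removed = sum(!keep_cell),
    genes_in = ncol(counts), genes_removed = sum(!keep_gene)
  )
  inform(paste0("qc_filter: removed ", log$cells_removed, "/", log$cells_in,
                " cells and ", log$genes_removed, "/", log$genes_in, " genes"))
  list(
    counts = sub[, keep_gene, drop = FALSE],
    annotation = annotation[keep_cell, , drop = FALSE],
    log = log
  )
}

#' Estimate the droplet multiplet rate from a species-mixing experiment
#'
#' In a barnyard design mixing equal numbers of cells from two species, a
#' barcode whose majority-species fraction of counts falls below
#' `purity_threshold` is a cross-species multiplet. Under equal mixing half
#' of all multiplets are same-species and unobservable, so the total rate is
#' twice the observed cross-species rate.
#'
#' @param counts Barcode-by-gene count matrix whose gene symbols carry a
#'   species prefix before `":"` (e.g. `A:GENE`, `B:GENE`).
#' @param purity_threshold Majority-species fraction below which a barcode is
#'   called a cross-species multiplet (default 0.9).
#' @return A one-row tibble: `rate` (total multiplet rate), `cross_rate`,
#'   `n_cross`, `n_cells`.
#' @export
estimate_multiplet_rate <- function(counts, purity_threshold = 0.9) {
  species <- sub(":.*$", "", colnames(counts))
  sp <- sort(unique(species))
  if (length(sp) < 2) {
    abort_format("single-species input: need two species gene namespaces")
  }
  per_species <- sapply(sp, function(s) {
    Matrix::rowSums(counts[, species == s, drop = FALSE])
  })
  totals <- rowSums(per_species)
  purity <- apply(per_species, 1L, max) / pmax(totals, 1)
  n_cross <- sum(totals > 0 & purity < purity_threshold)
  cross_rate <- n_cross / nrow(counts)
  tibble(
    rate = min(1, 2 * cross_rate), cross_rate = cross_rate,
    n_cross = n_cross, n_cells = nrow(counts)
  )
}

#' Library-size normalization and log transform
#'
#' Scales each cell's counts to a common total (10,000 by default) and
#' applies `log(1 + x)`. Sparsity is preserved.
#'
#' @param counts Cell-by-gene count matrix, QC-filtered.
#' @param scale Target per-cell total.
#' @return Cell-by-gene matrix of log-normalized expression.
#' @export
normalize_counts <- function(counts, scale = 1e4) {
  totals <- Matrix::rowSums(counts)
  if (any(totals == 0)) {
    abort_config(paste0(sum(totals == 0),
                        " cell(s) with zero total counts; run QC first"))
  }
  out <- log1p(Diagonal(x = scale / totals) %*% Matrix(counts, sparse = TRUE))
  dimnames(out) <- dimnames(counts)
  out
}

#' Select highly variable genes
#'
#' Genes are scored by their variance-to-mean dispersion, standardized
#' within 20 equal-count bins of mean expression so that selection is not a
#' proxy for expression level. The top `n_top` genes are returned with a
#' deterministic tie-break on gene-symbol order.
#'
#' @param expr Cell-by-gene normalized expression matrix.
#' @param n_top Number of genes to select; if it exceeds the gene count all
#'   genes are selected with a warning.
#' @param n_bins Number of equal-count mean bins (default 20).
#' @return A tibble ordered by rank: `gene`, `mean`, `variance`,
#'   `dispersion`, `scaled_dispersion`, `rank`, `selected`.
#' @export
select_hvg <- function(expr, n_top, n_bins = 20L) {
  if (n_top > ncol(expr)) {
    warn(paste0("n_top (", n_top, ") exceeds gene count (", ncol(expr),
                "): selecting all genes"))
    n_top <- ncol(expr)
  }
  n_bins <- max(1L, min(n_bins, ncol(expr) %/% 2L))
  mu <- as.numeric(Matrix::colMeans(expr))
  ex2 <- as.numeric(Matrix::colMeans(expr^2))
  v <- (ex2 - mu^2) * nrow(expr) / max(1, nrow(expr) - 1)
  disp <- ifelse(mu > 0, v / mu, 0)
  bin <- dplyr::ntile(mu, n_bins)
  tab <- tibble(gene = colnames(expr), mean = mu, variance = v,
                dispersion = disp, bin = bin) |>
    group_by(.data$bin) |>
    mutate(scaled_dispersion = {
      s <- sd(.data$dispersion)
      if (!is.finite(s) || s == 0) {
        .data$dispersion - mean(.data$dispersion)
      } else {
        (.data$dispersion - mean(.data$dispersion)) / s
      }
    }) |>
    ungroup() |>
    arrange(desc(.data$scaled_dispersion), .data$gene) |>
    mutate(rank = row_number(), selected = .data$rank <= n_top) |>
    select(-"bin")
  tab
}

#' Extract the selected gene set from a [select_hvg()] table
#' @param hvg A tibble from [select_hvg()].
#' @return Character vector of selected genes, in rank order.
#' @export
hvg_genes <- function(hvg) hvg$gene[hvg$selected]

#' Marker-panel cell-type assignment
#'
#' Scores each cell for each type as the unweighted mean normalized
#' expression of that type's marker genes, and assigns the argmax type. Ties
#' (including all-zero cells) are broken by the declared type order and
#' flagged low-confidence; the margin between the best and second-best score
#' is reported.
#'
#' @param expr Cell-by-gene normalized expression matrix.
#' @param panel Named list mapping cell type to marker gene symbols. Markers
#'   absent from the gene axis are dropped with a warning; a type losing all
#'   its markers is an error.
#' @param type_order Tie-break order (default: `names(panel)`).
#' @return A tibble: `barcode`, `cell_type`, `score`, `margin`,
#'   `low_confidence`.
#' @export
assign_cell_types <- function(expr, panel, type_order = names(panel)) {
  if (length(panel) == 0) abort_config("empty marker panel")
  panel <- panel[type_order]
  present <- lapply(panel, intersect, colnames(expr))
  dropped <- sum(lengths(panel)) - sum(lengths(present))
  if (dropped > 0) {
    warn(paste0(dropped, " marker(s) absent from the gene axis were dropped"))
  }
  empty <- names(present)[lengths(present) == 0]
  if (length(empty)) {
    abort_config(paste0("no markers present for type(s): ",
                        paste(empty, collapse = ", ")))
  }
  scores <- sapply(present, function(g) {
    as.numeric(Matrix::rowMeans(expr[, g, drop = FALSE]))
  })
  if (nrow(expr) == 1L) scores <- matrix(scores, nrow = 1L,
                                         dimnames = list(NULL, names(present)))
  best <- max.col(scores, ties.method = "first")
  top <- scores[cbind(seq_len(nrow(scores)), best)]
  second <- apply(scores, 1L, function(s) -sort(-s, partial = 2)[2])
  if (ncol(scores) == 1L) second <- rep(0, nrow(scores))
  tibble(
    barcode = rownames(expr),
    cell_type = colnames(scores)[best],
    score = top,
    margin = top - second,
    low_confidence = (top - second) <= 0
  )
}
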