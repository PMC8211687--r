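#' Reference-centered, clamped relative expression
#'
#' Subtracts from each gene the mean log-normalized expression over a
#' diploid reference population (e.g. normal hepatocytes) and clamps every
#' value to `[-cap, +cap]` so that a handful of extreme genes cannot
#' dominate a window average. This is the input to expression-inferred CNV
#' smoothing.
#'
#' @param expr Cell-by-gene normalized log expression matrix.
#' @param reference_ids Barcodes of the reference cells (must be present).
#' @param cap Symmetric clamp (default 3).
#' @return Dense cell-by-gene matrix of relative expression.
#' @export
relative_expression <- function(expr, reference_ids, cap = 3) {
  if (length(reference_ids) == 0) abort_config("empty reference set")
  missing_ref <- setdiff(reference_ids, rownames(expr))
  if (length(missing_ref)) {
    abort_config(paste0(length(missing_ref),
                        " reference barcode(s) absent from the matrix"))
  }
  if (cap <= 0) abort_config("cap must be > 0")
  ref_mean <- Matrix::colMeans(expr[reference_ids, , drop = FALSE])
  rel <- sweep(as.matrix(expr), 2L, as.numeric(ref_mean), "-")
  rel[rel > cap] <- cap
  rel[rel < -cap] <- -cap
  rel
}

#' Chromosome-ordered moving-average CNV profile
#'
#' Sorts genes by chromosomal position and, within each chromosome, averages
#' relative expression over sliding windows of `window` consecutive genes at
#' stride `step`. Chromosomes with fewer than `window` genes contribute a
#' single truncated window spanning all their genes, flagged in the window
#' map. Genes without a position are excluded (count logged).
#'
#' @param rel_expr Cell-by-gene relative expression from
#'   [relative_expression()].
#' @param positions Gene position tibble (see [read_gene_positions()]).
#' @param window Genes per window (default 100, the standard choice for
#'   expression-inferred CNV).
#' @param step Window stride (default 1, maximally overlapping).
#' @param reference_ids Optional reference barcodes recorded in the profile
#'   and used by [center_on_reference()].
#' @return A `cnv_profile`: list with `scores` (cell-by-window matrix),
#'   `window_map` (tibble: window, chrom, start_gene, end_gene, n_genes,
#'   truncated), `reference_ids`, `params`.
#' @export
cnv_moving_average <- function(rel_expr, positions, window = 100L, step = 1L,
                               reference_ids = NULL) {
  if (window < 1) abort_config("window must be >= 1")
  if (step < 1) abort_config("step must be >= 1")
  keep <- intersect(colnames(rel_expr), positions$gene)
  n_missing <- ncol(rel_expr) - length(keep)
  if (n_missing > 0) {
    inform(paste0("cnv_moving_average: ", n_missing,
                  " gene(s) without positions excluded"))
  }
  if (length(keep) == 0) abort_config("no gene has a position")
  pos <- positions |>
    filter(.data$gene %in% keep) |>
    arrange(.data$chrom, .data$start)

  maps <- list()
  for (ch in unique(pos$chrom)) {
    g <- pos$gene[pos$chrom == ch]
    n <- length(g)
    if (n >= window) {
      starts <- seq.int(1L, n - window + 1L, by = step)
      maps[[ch]] <- tibble(
        chrom = ch, start_idx = starts, end_idx = starts + window - 1L,
        start_gene = g[starts], end_gene = g[starts + window - 1L],
        n_genes = window, truncated = FALSE,
        genes = lapply(starts, function(s) g[s:(s + window - 1L)])
      )
    } else {
      maps[[ch]] <- tibble(
        chrom = ch, start_idx = 1L, end_idx = n,
        start_gene = g[[1]], end_gene = g[[n]],
        n_genes = n, truncated = TRUE, genes = list(g)
      )
    }
  }
  window_map <- bind_rows(maps) |>
    mutate(window = row_number()) |>
    select("window", "chrom", "start_gene", "end_gene", "n_genes",
           "truncated", "genes")

  # Window means as one sparse matrix product: W[gene, window] = 1/n_genes.
  gene_index <- setNames(seq_along(pos$gene), pos$gene)
  i <- unlist(lapply(window_map$genes, function(g) gene_index[g]),
              use.names = FALSE)
  j <- rep.int(window_map$window, window_map$n_genes)
  w <- sparseMatrix(i = i, j = j, x = rep.int(1 / window_map$n_genes,
                                              window_map$n_genes),
                    dims = c(nrow(pos), nrow(window_map)))
  scores <- as.matrix(rel_expr[, pos$gene, drop = FALSE] %*% w)
  colnames(scores) <- paste0("w", window_map$window)

  structure(
    list(
      scores = scores,
      window_map = select(window_map, -"genes"),
      reference_ids = reference_ids,
      params = list(window = window, step = step)
    ),
    class = "cnv_profile"
  )
}

#' @export
print.cnv_profile <- function(x, ...) {
  cat("cnv_profile:", nrow(x$scores), "cells x", ncol(x$scores), "windows (",
      length(unique(x$window_map$chrom)), "chromosomes )\n")
  invisible(x)
}

#' Center a CNV profile on its reference population
#'
#' Subtracts from every window the mean score of the reference cells, so the
#' reference population's mean profile is exactly zero per window and tumor
#' scores read as deviations from diploid.
#'
#' @param profile A `cnv_profile`.
#' @param reference_ids Reference barcodes; defaults to those recorded in
#'   the profile.
#' @return The centered `cnv_profile`.
#' @export
center_on_reference <- function(profile, reference_ids = NULL) {
  reference_ids <- reference_ids %||% profile$reference_ids
  if (is.null(reference_ids) || length(reference_ids) == 0) {
    abort_config("no reference cells recorded or supplied")
  }
  missing_ref <- setdiff(reference_ids, rownames(profile$scores))
  if (length(missing_ref)) {
    abort_config("reference barcodes absent from the profile")
  }
  ref_mean <- colMeans(profile$scores[reference_ids, , drop = FALSE])
  profile$scores <- sweep(profile$scores, 2L, ref_mean, "-")
  profile$reference_ids <- reference_ids
  profile
}

#' Cluster cells into CNV groups
#'
#' Agglomerative hierarchical clustering (Euclidean distance, average
#' linkage) of cells on their window scores, cut at `k` groups or at a
#' dendrogram `height`. The dendrogram is exportable as Newick via
#' [as_newick()].
#'
#' @param profile A `cnv_profile`.
#' @param k Number of groups (or `NULL` if `height` is given).
#' @param height Cut height alternative to `k`.
#' @return A `cnv_grouping`: list with `groups` (tibble: barcode, group),
#'   `hclust`, `k`.
#' @export
cluster_cnv_groups <- function(profile, k = NULL, height = NULL) {
  scores <- profile$scores
  if (nrow(scores) < 2) abort_config("need >= 2 cells to cluster")
  if (!is.null(k) && k > nrow(scores)) {
    abort_config(paste0("k (", k, ") exceeds cell count (", nrow(scores), ")"))
  }
  if (is.null(k) && is.null(height)) abort_config("supply k or height")
  hc <- hclust(dist(scores), method = "average")
  labels <- if (!is.null(k)) cutree(hc, k = k) else cutree(hc, h = height)
  structure(
    list(
      groups = tibble(barcode = rownames(scores),
                      group = as.integer(labels[rownames(scores)])),
      hclust = hc,
      k = length(unique(labels))
    ),
    class = "cnv_grouping"
  )
}

#' Export a clustering dendrogram as a Newick string
#'
#' @param x A `cnv_grouping`, `lcsc_grouping` or `hclust` object.
#' @param path Optional file to write to.
#' @return The Newick string (invisibly when `path` is given).
#' @export
as_newick <- function(x, path = NULL) {
  hc <- if (inherits(x, "hclust")) x else x$hclust
  tr <- ape::as.phylo(hc)
  nwk <- ape::write.tree(tr)
  if (!is.null(path)) {
    writeLines(nwk, path)
    return(invisible(nwk))
  }
  nwk
}
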