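#' The liver cancer stem cell (LCSC) marker panel
#'
#' The nine-marker panel used to stratify tumor cells: EPCAM, KRT19,
#' ALDH1A1, CD13, CD24, CD44, CD47, CD90 and CD133. Protein names are mapped
#' to transcript symbols (CD13 -> ANPEP, CD90 -> THY1, CD133 -> PROM1)
#' because count matrices carry gene symbols.
#'
#' @param as_protein If `TRUE`, return the protein names instead of the
#'   transcript symbols.
#' @return Character vector of nine gene symbols.
#' @seealso [lcsc_aliases()]
#' @export
lcsc_panel <- function(as_protein = FALSE) {
  al <- lcsc_aliases()
  if (as_protein) al$protein else al$symbol
}

#' Protein-to-transcript alias table for the LCSC panel
#' @return A tibble with columns `protein` and `symbol`.
#' @export
lcsc_aliases <- function() {
  tibble(
    protein = c("EPCAM", "KRT19", "ALDH1A1", "CD13", "CD24", "CD44", "CD47",
                "CD90", "CD133"),
    symbol = c("EPCAM", "KRT19", "ALDH1A1", "ANPEP", "CD24", "CD44", "CD47",
               "THY1", "PROM1")
  )
}

#' Stratify tumor cells by a stem-cell marker panel
#'
#' Unsupervised hierarchical clustering (Euclidean distance, average
#' linkage) of cells on the normalized expression of a marker panel, cut at
#' `k` groups. When per-cell sample labels are supplied, a sample-by-group
#' contingency table is attached, mirroring the per-case tabulation of
#' marker groups.
#'
#' @param expr Cell-by-gene normalized expression matrix (tumor cells).
#' @param panel Character vector of panel gene symbols (default
#'   [lcsc_panel()]); absent genes are dropped with a warning, none present
#'   is an error. Clustering is invariant to panel gene order.
#' @param k Number of groups.
#' @param sample Optional per-cell sample labels (aligned to `expr` rows or
#'   named by barcode).
#' @return An `lcsc_grouping`: list with `groups` (tibble: barcode, group),
#'   `hclust`, `panel_used`, and `contingency` (tibble or `NULL`).
#' @export
lcsc_groups <- function(expr, panel = lcsc_panel(), k, sample = NULL) {
  if (nrow(expr) < 2) abort_config("need >= 2 cells")
  if (k > nrow(expr)) abort_config("k exceeds cell count")
  used <- intersect(sort(panel), colnames(expr))
  if (length(used) == 0) {
    abort_config("no panel gene is present in the matrix")
  }
  if (length(used) < length(unique(panel))) {
    warn(paste0(length(unique(panel)) - length(used),
                " panel gene(s) absent from the matrix were dropped"))
  }
  sub <- as.matrix(expr[, used, drop = FALSE])
  hc <- hclust(dist(sub), method = "average")
  labels <- cutree(hc, k = k)
  groups <- tibble(barcode = rownames(sub),
                   group = as.integer(labels[rownames(sub)]))
  contingency <- NULL
  if (!is.null(sample)) {
    smp <- if (!is.null(names(sample))) sample[groups$barcode] else sample
    contingency <- groups |>
      mutate(sample = smp) |>
      count(.data$sample, .data$group) |>
      tidyr::pivot_wider(names_from = "group", values_from = "n",
                         names_prefix = "group_", values_fill = 0L)
  }
  structure(
    list(groups = groups, hclust = hc, panel_used = used,
         contingency = contingency),
    class = "lcsc_grouping"
  )
}

#' Per-sample cell-type composition
#'
#' The proportion of each cell type among annotated cells of each sample,
#' over a declared type set (proportions sum to one per sample). Optional
#' subset proportions (e.g. CD8 T within all T cells) are computed within
#' their parent type set.
#'
#' @param annotation Tibble with `barcode`, `sample`, `cell_type`.
#' @param type_set Types to tabulate (default: all observed). Unknown types
#'   are an error. With fewer than 3 types a warning reminds that the two
#'   proportions are exactly complementary (compositional artifact, not
#'   biology).
#' @param subsets Optional named list: subset name -> list(subset = types,
#'   parent = types); the proportion of subset cells among parent cells is
#'   appended with `cell_type` set to the subset name and `within` to the
#'   parent.
#' @return A `composition` tibble: `sample`, `cell_type`, `n`, `proportion`,
#'   `within` (`"all"` for the main type set).
#' @export
composition <- function(annotation, type_set = NULL, subsets = NULL) {
  observed <- unique(annotation$cell_type)
  type_set <- type_set %||% sort(observed)
  unknown <- setdiff(type_set, observed)
  if (length(unknown)) {
    abort_config(paste0("unknown cell type(s) in type_set: ",
                        paste(unknown, collapse = ", ")))
  }
  if (length(type_set) < 3) {
    warn("with 2 types the two proportions are exactly complementary (r = -1 by construction)")
  }
  base <- annotation |>
    filter(.data$cell_type %in% type_set) |>
    count(.data$sample, .data$cell_type) |>
    group_by(.data$sample) |>
    mutate(proportion = .data$n / sum(.data$n)) |>
    ungroup() |>
    tidyr::complete(sample = unique(annotation$sample),
                    cell_type = type_set,
                    fill = list(n = 0L, proportion = 0)) |>
    mutate(within = "all")
  out <- base
  for (nm in names(subsets)) {
    sdef <- subsets[[nm]]
    sub <- annotation |>
      filter(.data$cell_type %in% sdef$parent) |>
      group_by(.data$sample) |>
      summarise(n = sum(.data$cell_type %in% sdef$subset),
                proportion = .data$n / dplyr::n(), .groups = "drop") |>
      mutate(cell_type = nm, within = paste(sdef$parent, collapse = "+"))
    out <- bind_rows(out, sub)
  }
  class(out) <- c("composition", class(out))
  out
}

#' Correlation between two cell-type proportions across samples
#'
#' Two-sided Pearson correlation between the per-sample proportions of two
#' cell types (e.g. tumor-infiltrating macrophages vs T cells), with the
#' p-value from the t distribution on n - 2 degrees of freedom. A p-value
#' underflowing double precision is reported as the smallest positive
#' double rather than 0 or NaN.
#'
#' @param comp A [composition()] tibble.
#' @param type_a,type_b The two cell types to correlate.
#' @return One-row tibble: `type_a`, `type_b`, `n_samples`, `r`, `p`.
#' @export
proportion_correlation <- function(comp, type_a, type_b) {
  wide <- comp |>
    filter(.data$cell_type %in% c(type_a, type_b)) |>
    select("sample", "cell_type", "proportion") |>
    tidyr::pivot_wider(names_from = "cell_type", values_from = "proportion")
  for (t in c(type_a, type_b)) {
    if (!t %in% names(wide)) {
      abort_config(paste0("type '", t, "' absent from the composition table"))
    }
  }
  a <- wide[[type_a]]
  b <- wide[[type_b]]
  n <- sum(stats::complete.cases(a, b))
  if (n < 3) abort_config("need >= 3 samples")
  if (sd(a) == 0 || sd(b) == 0) {
    abort_config("zero variance in a proportion vector: r undefined")
  }
  ct <- suppressWarnings(cor.test(a, b, method = "pearson",
                                  alternative = "two.sided"))
  tibble(
    type_a = type_a, type_b = type_b, n_samples = n,
    r = unname(ct$estimate),
    p = max(ct$p.value, .Machine$double.xmin)
  )
}
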