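#' Read a cell-by-gene UMI count matrix from a Matrix Market triplet
#'
#' Reads the standard `matrix.mtx` + `barcodes.tsv` + `features.tsv` triplet
#' used for droplet single-cell data. The on-disk 10x convention stores genes
#' as rows; the in-memory convention here is cells as rows, because every
#' downstream statistic is a per-cell aggregation. Orientation is
#' auto-detected from the axis lengths and the matrix is transposed on read
#' when needed. When the matrix is square the two orientations cannot be told
#' apart, so an explicit `orientation` is required.
#'
#' @param mtx_path Path to the Matrix Market coordinate file.
#' @param barcodes_path Path to the barcodes file (one barcode per line).
#' @param features_path Path to the features file; if it has two or more
#'   tab-separated columns the second is taken as the gene symbol (10x
#'   convention: id, symbol, type), otherwise the first.
#' @param orientation `NULL` (auto-detect) or one of `"cells"` / `"genes"`,
#'   stating which axis the on-disk rows are. Required for square matrices.
#' @return A sparse `dgCMatrix` with cells as rows, barcodes as rownames and
#'   gene symbols as colnames. All entries are non-negative integers.
#' @export
read_count_matrix <- function(mtx_path, barcodes_path, features_path,
                              orientation = NULL) {
  for (p in c(mtx_path, barcodes_path, features_path)) {
    if (!file.exists(p)) abort_format(paste0("file not found: ", p))
  }
  m <- Matrix::readMM(mtx_path)
  barcodes <- readLines(barcodes_path)
  feat <- readLines(features_path)
  genes <- vapply(strsplit(feat, "\t", fixed = TRUE), function(f) {
    if (length(f) >= 2) f[[2]] else f[[1]]
  }, character(1))

  if (anyDuplicated(barcodes)) {
    abort_format(paste0("duplicate barcodes in ", barcodes_path))
  }
  if (anyDuplicated(genes)) {
    abort_format(paste0("duplicate gene symbols in ", features_path))
  }

  nb <- length(barcodes)
  ng <- length(genes)
  if (is.null(orientation)) {
    if (nb == ng) {
      abort_format(paste0(
        "matrix is square (", nb, " x ", ng, "): orientation cannot be ",
        "auto-detected, pass orientation = \"cells\" or \"genes\""
      ))
    }
    if (nrow(m) == nb && ncol(m) == ng) {
      orientation <- "cells"
    } else if (nrow(m) == ng && ncol(m) == nb) {
      orientation <- "genes"
    } else {
      abort_format(paste0(
        "dimensions of ", mtx_path, " (", nrow(m), " x ", ncol(m), ") match ",
        "neither ", nb, " barcodes (", barcodes_path, ") nor ", ng,
        " features (", features_path, ") on either axis"
      ))
    }
  } else {
    orientation <- match.arg(orientation, c("cells", "genes"))
    dims_ok <- if (orientation == "cells") {
      nrow(m) == nb && ncol(m) == ng
    } else {
      nrow(m) == ng && ncol(m) == nb
    }
    if (!dims_ok) {
      abort_format(paste0(
        "declared orientation \"", orientation, "\" inconsistent with ",
        mtx_path, " dimensions ", nrow(m), " x ", ncol(m)
      ))
    }
  }
  if (orientation == "genes") m <- Matrix::t(m)
  inform(paste0(
    "read ", nrow(m), " cells x ", ncol(m), " genes (on-disk rows were ",
    orientation, ")"
  ))

  m <- methods::as(methods::as(m, "CsparseMatrix"), "generalMatrix")
  vals <- m@x
  if (any(vals < 0) || any(vals != round(vals))) {
    abort_format(paste0("non-integer or negative entries in ", mtx_path))
  }
  dimnames(m) <- list(barcodes, genes)
  m
}

#' Write a count matrix as a Matrix Market triplet
#'
#' Writes `matrix.mtx`, `barcodes.tsv` and `features.tsv` under `dir`, using
#' the on-disk 10x convention of genes as rows. The features file carries the
#' gene symbol in both the id and symbol columns.
#'
#' @param counts Cell-by-gene sparse or dense matrix with dimnames.
#' @param dir Output directory, created if missing.
#' @return Invisibly, the three file paths.
#' @export
write_count_matrix <- function(counts, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("matrix.mtx", "barcodes.tsv", "features.tsv"))
  Matrix::writeMM(methods::as(Matrix::t(Matrix(counts, sparse = TRUE)), "generalMatrix"),
                  paths[[1]])
  writeLines(rownames(counts), paths[[2]])
  writeLines(paste(colnames(counts), colnames(counts), "Gene Expression",
                   sep = "\t"), paths[[3]])
  invisible(paths)
}

#' Write a result table as deterministic TSV
#'
#' Tab-separated, header row, UTF-8, `.` decimal. Rows are stably sorted on
#' the declared key columns so identical inputs always produce byte-identical
#' files; an empty table yields a header-only file.
#'
#' @param records A data frame.
#' @param path Output path.
#' @param key Character vector of columns to sort on (default: none, input
#'   order kept).
#' @return Invisibly, `path`.
#' @export
write_table <- function(records, path, key = NULL) {
  records <- as_tibble(records)
  if (!is.null(key)) {
    missing_key <- setdiff(key, names(records))
    if (length(missing_key)) {
      abort_format(paste0("sort key column(s) absent: ",
                          paste(missing_key, collapse = ", ")))
    }
    records <- arrange(records, across(all_of(key)))
  }
  readr::write_tsv(records, path, progress = FALSE)
  invisible(path)
}

#' Read a gene position table (BED-like TSV)
#'
#' Expects at least four columns: chrom, start, end, gene, with an optional
#' fifth strand column. Coordinates are 0-based half-open. Records are
#' returned sorted by (chrom, start); duplicate gene symbols and empty
#' intervals are rejected with the offending line number.
#'
#' @param bed_path Path to the table (no header).
#' @return A tibble with columns `chrom`, `start`, `end`, `gene`, `strand`.
#' @export
read_gene_positions <- function(bed_path) {
  if (!file.exists(bed_path)) abort_format(paste0("file not found: ", bed_path))
  raw <- readr::read_tsv(bed_path, col_names = FALSE, progress = FALSE,
                         show_col_types = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  if (ncol(raw) < 4) {
    abort_format(paste0(bed_path, ": expected >= 4 columns, got ", ncol(raw)))
  }
  pos <- tibble(
    chrom = raw[[1]],
    start = as.numeric(raw[[2]]),
    end = as.numeric(raw[[3]]),
    gene = raw[[4]],
    strand = if (ncol(raw) >= 6) raw[[6]] else if (ncol(raw) >= 5 &&
      all(raw[[5]] %in% c("+", "-"))) raw[[5]] else "+",
    .line = seq_len(nrow(raw))
  )
  bad <- which(!(pos$start < pos$end))
  if (length(bad)) {
    abort_format(paste0(bed_path, " line ", bad[[1]], ": start >= end (",
                        pos$start[bad[[1]]], " >= ", pos$end[bad[[1]]], ")"))
  }
  dup <- pos$gene[duplicated(pos$gene)]
  if (length(dup)) {
    abort_format(paste0(bed_path, ": duplicate gene symbol(s): ",
                        paste(unique(dup), collapse = ", ")))
  }
  pos |>
    arrange(.data$chrom, .data$start) |>
    select(-".line")
}

#' Read a per-cell annotation table
#'
#' A TSV with a header; must contain at least `barcode`, and typically
#' `sample` and `cell_type` plus the QC metrics `n_genes` and `mito_frac`.
#'
#' @param path Path to the TSV.
#' @return A tibble, one row per barcode.
#' @export
read_cell_annotation <- function(path) {
  ann <- readr::read_tsv(path, progress = FALSE, show_col_types = FALSE)
  if (!"barcode" %in% names(ann)) {
    abort_format(paste0(path, ": missing required column 'barcode'"))
  }
  if (anyDuplicated(ann$barcode)) {
    abort_format(paste0(path, ": duplicate barcodes"))
  }
  if ("mito_frac" %in% names(ann) &&
      any(ann$mito_frac < 0 | ann$mito_frac > 1, na.rm = TRUE)) {
    abort_format(paste0(path, ": mito_frac outside [0, 1]"))
  }
  ann
}

#' Read a ligand-receptor pair table
#'
#' A TSV with header columns `ligand` and `receptor`; optional `axis` (a
#' checkpoint name or pair id, defaulting to `ligand-receptor`) and
#' `category` (co-stimulatory / co-inhibitory / generic).
#'
#' @param path Path to the TSV.
#' @return A tibble with columns `axis`, `ligand`, `receptor`, `category`.
#' @export
read_lr_pairs <- function(path) {
  tab <- readr::read_tsv(path, progress = FALSE, show_col_types = FALSE)
  need <- setdiff(c("ligand", "receptor"), names(tab))
  if (length(need)) {
    abort_format(paste0(path, ": missing column(s): ",
                        paste(need, collapse = ", ")))
  }
  if (any(!nzchar(tab$ligand)) || any(!nzchar(tab$receptor))) {
    abort_format(paste0(path, ": empty gene symbols"))
  }
  tab <- as_tibble(tab)
  if (!"axis" %in% names(tab)) {
    tab$axis <- paste(tab$ligand, tab$receptor, sep = "-")
  }
  if (!"category" %in% names(tab)) tab$category <- "generic"
  if (anyDuplicated(tab[, c("ligand", "receptor")])) {
    abort_format(paste0(path, ": duplicate (ligand, receptor) pairs"))
  }
  tab[, c("axis", "ligand", "receptor", "category")]
}
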