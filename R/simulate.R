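#' Simulation configuration for multi-patient tumor single-cell data
#'
#' Builds the configuration consumed by [simulate_tme()]. The defaults
#' emulate a desk-scale version of a multi-case hepatocellular-carcinoma
#' cohort: 8 patients, ten cell types whose tumor compartment is
#' patient-private (through patient-specific copy-number segments) while
#' immune and stromal states are shared, a planted immune-checkpoint
#' ligand-receptor axis, mitochondrial genes, and a small droplet multiplet
#' rate.
#'
#' Counts are gamma-Poisson (negative binomial) with gene-level log-normal
#' base means and a per-cell log-normal library-size factor. Marker genes are
#' up-weighted `marker_fold`-fold in their own type; planted axis ligand
#' (receptor) genes are up-weighted in the sender (receiver) type, with `"*"`
#' meaning all types; copy-number segments scale the NB mean of spanned genes
#' by `2^log2fc` in tumor cells of the affected patient.
#'
#' @param seed Integer seed; identical seed + config give identical output.
#' @param n_patients Number of patients.
#' @param cells_per_type Named integer vector, cells per type per patient, or
#'   a patients-by-types integer matrix for per-patient compositions.
#' @param n_genes Number of genes; chromosomes are simulated as contiguous
#'   blocks of `genes_per_chrom` genes at 10-kb spacing, in declaration order.
#' @param genes_per_chrom Genes per simulated chromosome.
#' @param base_mean_meanlog,base_mean_sdlog Log-normal parameters of the
#'   per-gene base NB mean.
#' @param dispersion NB size parameter (smaller = noisier).
#' @param library_sdlog Standard deviation (log scale) of the per-cell
#'   library-size factor.
#' @param marker_fold Fold-change of marker genes in their own type (> 1).
#' @param markers_per_type Markers auto-assigned per type when `markers` is
#'   `NULL` (symbols `<type>.mk1`, ...); default 10, the order of magnitude
#'   of published per-type marker tables.
#' @param markers Optional named list type -> marker gene symbols; symbols
#'   not already present are planted by renaming unused genes.
#' @param planted_axes Tibble with columns `ligand`, `receptor`, `sender`,
#'   `receiver`, `fold`; axis gene symbols are planted like markers. Axis
#'   genes get base mean `axis_base_mean` (checkpoint genes are moderately
#'   expressed, not drawn from the genome-wide tail).
#' @param axis_base_mean Base NB mean of planted axis genes.
#' @param marker_base_mean Base NB mean of marker genes (canonical identity
#'   markers are moderately expressed, not drawn from the genome-wide tail).
#' @param cnv_segments Tibble with columns `patient` (1-based index), `chrom`,
#'   `start_gene`, `end_gene` (1-based gene indices within the chromosome,
#'   inclusive) and `log2fc` (typically in -1, -0.5, 0.5, 1).
#' @param n_mito,mito_mean Number of mitochondrial genes (symbols `MT-1`,
#'   ...) and their common base mean (they are highly expressed).
#' @param doublet_rate Fraction of extra barcodes formed by summing the
#'   counts of two uniformly chosen cells.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_patients = 8L,
                       cells_per_type = c(
                         Tumor = 40L, CD8T = 20L, CD4T = 15L, Treg = 10L,
                         NK = 10L, B = 10L, TAM = 20L, Endothelial = 10L,
                         Fibroblast = 10L, Hepatocyte = 25L
                       ),
                       n_genes = 1250L,
                       genes_per_chrom = 250L,
                       base_mean_meanlog = log(0.5),
                       base_mean_sdlog = 1.2,
                       dispersion = 2,
                       library_sdlog = 0.3,
                       marker_fold = 8,
                       markers_per_type = 10L,
                       markers = NULL,
                       planted_axes = tibble(
                         ligand = "NECTIN2", receptor = "TIGIT",
                         sender = "Tumor", receiver = "CD8T", fold = 8
                       ),
                       axis_base_mean = 1,
                       marker_base_mean = 1,
                       cnv_segments = NULL,
                       n_mito = 10L,
                       mito_mean = 5,
                       doublet_rate = 0.006) {
  types <- if (is.matrix(cells_per_type)) colnames(cells_per_type) else names(cells_per_type)
  if (is.null(cnv_segments)) {
    cnv_segments <- default_cnv_segments(n_patients, n_genes, genes_per_chrom)
  }
  cfg <- list(
    seed = seed, n_patients = n_patients, cells_per_type = cells_per_type,
    n_genes = n_genes, genes_per_chrom = genes_per_chrom,
    base_mean_meanlog = base_mean_meanlog, base_mean_sdlog = base_mean_sdlog,
    dispersion = dispersion, library_sdlog = library_sdlog,
    marker_fold = marker_fold, markers_per_type = markers_per_type,
    markers = markers, planted_axes = planted_axes,
    axis_base_mean = axis_base_mean, marker_base_mean = marker_base_mean,
    cnv_segments = cnv_segments,
    n_mito = n_mito, mito_mean = mito_mean, doublet_rate = doublet_rate,
    types = types
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

# One patient-private segment each. Lesions avoid the last chromosome,
# whose tail carries the planted identity programs (markers, axis genes,
# mitochondria): expression-proxy CNV is confounded wherever an identity
# program sits inside a lesion. When patients outnumber the usable
# chromosomes the offset shifts per cycle so shared-chromosome lesions stay
# distinguishable; signs alternate with the patient index.
default_cnv_segments <- function(n_patients, n_genes, genes_per_chrom) {
  n_chrom <- max(1L, n_genes %/% genes_per_chrom)
  usable <- max(1L, n_chrom - as.integer(n_chrom > 1L))
  p <- seq_len(n_patients)
  cycle <- (p - 1L) %/% usable
  start <- pmin(26L + 50L * cycle, pmax(1L, genes_per_chrom - 29L))
  tibble(
    patient = p,
    chrom = paste0("chr", 1L + (p - 1L) %% usable),
    start_gene = start,
    end_gene = pmin(start + 149L, genes_per_chrom),
    log2fc = ifelse(p %% 2L == 1L, 1, -1) * ifelse(cycle %% 2L == 0L, 1, -1)
  )
}

validate_sim_config <- function(cfg) {
  cpt <- cfg$cells_per_type
  if (is.matrix(cpt)) {
    if (nrow(cpt) != cfg$n_patients) {
      abort_config("cells_per_type matrix must have n_patients rows")
    }
    if (any(cpt < 0)) abort_config("cell counts must be >= 0")
  } else if (any(cpt < 1)) {
    abort_config("cells_per_type entries must be >= 1")
  }
  if (cfg$doublet_rate < 0 || cfg$doublet_rate > 1) {
    abort_config("doublet_rate must lie in [0, 1]")
  }
  if (cfg$marker_fold <= 0) abort_config("marker_fold must be > 0")
  if (nrow(cfg$planted_axes) &&
      (any(cfg$planted_axes$fold <= 0))) {
    abort_config("planted axis folds must be > 0")
  }
  n_chrom <- max(1L, cfg$n_genes %/% cfg$genes_per_chrom)
  chrom_len <- chrom_lengths(cfg$n_genes, cfg$genes_per_chrom)
  seg <- cfg$cnv_segments
  if (nrow(seg)) {
    bad_chr <- !seg$chrom %in% names(chrom_len)
    if (any(bad_chr)) {
      abort_config(paste0("cnv segment on nonexistent chromosome: ",
                          paste(unique(seg$chrom[bad_chr]), collapse = ", ")))
    }
    over <- seg$end_gene > chrom_len[seg$chrom] | seg$start_gene < 1 |
      seg$start_gene > seg$end_gene
    if (any(over)) {
      abort_config("cnv segment gene range outside its chromosome")
    }
    if (any(!seg$patient %in% seq_len(cfg$n_patients))) {
      abort_config("cnv segment references a nonexistent patient")
    }
  }
  invisible(cfg)
}

# Number of genes on each simulated chromosome; the remainder after whole
# blocks of genes_per_chrom is appended to the last chromosome.
chrom_lengths <- function(n_genes, genes_per_chrom) {
  n_chrom <- max(1L, n_genes %/% genes_per_chrom)
  len <- rep(genes_per_chrom, n_chrom)
  len[n_chrom] <- n_genes - genes_per_chrom * (n_chrom - 1L)
  names(len) <- paste0("chr", seq_len(n_chrom))
  len
}

#' Simulate a multi-patient tumor-microenvironment count matrix
#'
#' Draws a cell-by-gene UMI count matrix with planted ground truth according
#' to a [sim_config()]. Gene positions are contiguous on simulated
#' chromosomes (10-kb spacing, declaration order). Doublets are appended as
#' extra barcodes formed by summing the counts of two uniformly chosen cells.
#'
#' @param config A `sim_config`.
#' @return A `tme_sim` list with elements `counts` (sparse cell x gene
#'   matrix), `truth` (tibble: barcode, patient, cell_type, is_doublet),
#'   `gene_positions` (tibble as in [read_gene_positions()]), `markers`
#'   (named list type -> symbols), `axes`, `cnv_segments`, `mito_genes`,
#'   and `config`.
#' @export
simulate_tme <- function(config = sim_config()) {
  validate_sim_config(config)
  types <- config$types
  n_genes <- config$n_genes

  # Gene symbols: generic G#### with special genes renamed from the tail:
  # [axis genes][markers][mito] so default CNV segments never span them.
  genes <- sprintf("G%04d", seq_len(n_genes))
  ptr <- n_genes
  mito_idx <- integer(0)
  if (config$n_mito > 0) {
    mito_idx <- (ptr - config$n_mito + 1L):ptr
    genes[mito_idx] <- paste0("MT-", seq_along(mito_idx))
    ptr <- ptr - config$n_mito
  }
  markers <- config$markers
  if (is.null(markers)) {
    markers <- lapply(setNames(types, types), function(t) {
      paste0(t, ".mk", seq_len(config$markers_per_type))
    })
  }
  marker_syms <- unique(unlist(markers, use.names = FALSE))
  new_marks <- setdiff(marker_syms, genes)
  if (length(new_marks)) {
    idx <- (ptr - length(new_marks) + 1L):ptr
    genes[idx] <- new_marks
    ptr <- ptr - length(new_marks)
  }
  axis_syms <- unique(c(config$planted_axes$ligand, config$planted_axes$receptor))
  new_axis <- setdiff(axis_syms, genes)
  if (length(new_axis)) {
    idx <- (ptr - length(new_axis) + 1L):ptr
    genes[idx] <- new_axis
    ptr <- ptr - length(new_axis)
  }
  if (ptr < 0) abort_config("n_genes too small for the requested special genes")

  chrom_len <- chrom_lengths(n_genes, config$genes_per_chrom)
  chrom <- rep(names(chrom_len), chrom_len)
  within <- unlist(lapply(chrom_len, seq_len), use.names = FALSE)
  gene_positions <- tibble(
    chrom = chrom,
    start = (within - 1L) * 10000,
    end = (within - 1L) * 10000 + 1000,
    gene = genes,
    strand = "+"
  )

  cpt <- config$cells_per_type
  if (!is.matrix(cpt)) {
    cpt <- matrix(rep(cpt, each = config$n_patients), nrow = config$n_patients,
                  dimnames = list(NULL, names(config$cells_per_type)))
  }

  with_seed(config$seed, {
    base_mean <- rlnorm(n_genes, config$base_mean_meanlog, config$base_mean_sdlog)
    base_mean[mito_idx] <- config$mito_mean
    mk_idx <- match(intersect(marker_syms, genes), genes)
    base_mean[mk_idx] <- config$marker_base_mean
    if (length(axis_syms)) base_mean[match(axis_syms, genes)] <- config$axis_base_mean

    # Per-type mean multipliers (markers + axis folds), patient-independent.
    type_mult <- sapply(setNames(types, types), function(t) {
      m <- rep(1, n_genes)
      mk <- intersect(markers[[t]] %||% character(0), genes)
      m[match(mk, genes)] <- m[match(mk, genes)] * config$marker_fold
      ax <- config$planted_axes
      if (nrow(ax)) {
        for (i in seq_len(nrow(ax))) {
          if (ax$sender[i] == "*" || ax$sender[i] == t) {
            j <- match(ax$ligand[i], genes)
            m[j] <- m[j] * ax$fold[i]
          }
          if (ax$receiver[i] == "*" || ax$receiver[i] == t) {
            j <- match(ax$receptor[i], genes)
            m[j] <- m[j] * ax$fold[i]
          }
        }
      }
      m
    })

    # Per-patient CNV multiplier on tumor cells.
    seg <- config$cnv_segments
    cnv_mult <- matrix(1, nrow = config$n_patients, ncol = n_genes)
    if (nrow(seg)) {
      chrom_offset <- c(0L, cumsum(chrom_len))[seq_along(chrom_len)]
      names(chrom_offset) <- names(chrom_len)
      for (i in seq_len(nrow(seg))) {
        gidx <- (chrom_offset[[seg$chrom[i]]] + seg$start_gene[i]):(
          chrom_offset[[seg$chrom[i]]] + seg$end_gene[i])
        cnv_mult[seg$patient[i], gidx] <-
          cnv_mult[seg$patient[i], gidx] * 2^seg$log2fc[i]
      }
    }

    blocks <- list()
    truth <- list()
    for (p in seq_len(config$n_patients)) {
      for (t in types) {
        nc <- cpt[p, t]
        if (nc == 0) next
        mu_g <- base_mean * type_mult[, t]
        if (t == "Tumor") mu_g <- mu_g * cnv_mult[p, ]
        lib <- rlnorm(nc, 0, config$library_sdlog)
        mu <- lib %o% mu_g
        cnt <- matrix(
          rnbinom(length(mu), size = config$dispersion, mu = mu),
          nrow = nc
        )
        bc <- sprintf("P%d-%s-%03d", p, t, seq_len(nc))
        rownames(cnt) <- bc
        blocks[[length(blocks) + 1L]] <- cnt
        truth[[length(truth) + 1L]] <- tibble(
          barcode = bc, patient = paste0("P", p), cell_type = t,
          is_doublet = FALSE
        )
      }
    }
    counts <- do.call(rbind, blocks)
    truth <- bind_rows(truth)

    n_d <- round(config$doublet_rate * nrow(counts))
    if (n_d > 0) {
      i1 <- sample.int(nrow(counts), n_d, replace = TRUE)
      i2 <- sample.int(nrow(counts), n_d, replace = TRUE)
      dbl <- counts[i1, , drop = FALSE] + counts[i2, , drop = FALSE]
      rownames(dbl) <- sprintf("DBL-%03d", seq_len(n_d))
      truth <- bind_rows(truth, tibble(
        barcode = rownames(dbl),
        patient = truth$patient[i1],
        cell_type = paste(truth$cell_type[i1], truth$cell_type[i2], sep = "+"),
        is_doublet = TRUE
      ))
      counts <- rbind(counts, dbl)
    }
    colnames(counts) <- genes
    counts <- methods::as(Matrix(counts, sparse = TRUE), "generalMatrix")

    structure(
      list(
        counts = counts, truth = truth, gene_positions = gene_positions,
        markers = markers, axes = config$planted_axes,
        cnv_segments = config$cnv_segments,
        mito_genes = genes[mito_idx], config = config
      ),
      class = "tme_sim"
    )
  })
}

#' @export
print.tme_sim <- function(x, ...) {
  cat("tme_sim:", nrow(x$counts), "cells x", ncol(x$counts), "genes,",
      x$config$n_patients, "patients,", sum(x$truth$is_doublet),
      "doublets\n")
  invisible(x)
}

#' Simulate a two-species barnyard mixing experiment
#'
#' Mixes cells of two species with disjoint gene namespaces (`A:`/`B:`
#' prefixes) to plant a known droplet multiplet rate. Pure cells express only
#' their own species' genes apart from Poisson cross-species ambient
#' contamination; doublets are extra barcodes summing two cells drawn
#' uniformly from the pooled population, so about half of them are
#' cross-species and detectable.
#'
#' @param n_a,n_b Pure cells of species A and B.
#' @param doublet_rate Fraction of barcodes that are doublets.
#' @param ambient_rate Cross-species ambient contamination, as a fraction of
#'   the other species' expression profile (default 0.5%).
#' @param n_genes Genes per species.
#' @param dispersion NB size parameter.
#' @param seed Integer seed.
#' @return A `barnyard_sim` list with `counts` (sparse barcode x gene) and
#'   `truth` (tibble: barcode, species, is_doublet, is_cross_species) and
#'   `planted_rate` (doublets / total barcodes).
#' @export
simulate_barnyard <- function(n_a = 500L, n_b = 500L, doublet_rate = 0.006,
                              ambient_rate = 0.005, n_genes = 100L,
                              dispersion = 2, seed = 1L) {
  if (doublet_rate < 0 || doublet_rate > 1) {
    abort_config("doublet_rate must lie in [0, 1]")
  }
  if (ambient_rate < 0) abort_config("ambient_rate must be >= 0")
  with_seed(seed, {
    genes <- c(paste0("A:g", seq_len(n_genes)), paste0("B:g", seq_len(n_genes)))
    mean_a <- rlnorm(n_genes, 0, 1)
    mean_b <- rlnorm(n_genes, 0, 1)
    draw <- function(n, own_mean, other_mean, own_first) {
      lib <- rlnorm(n, 0, 0.3)
      own <- matrix(rnbinom(n * n_genes, size = dispersion,
                            mu = lib %o% own_mean), nrow = n)
      amb <- matrix(rpois(n * n_genes, lambda = ambient_rate * lib %o% other_mean),
                    nrow = n)
      if (own_first) cbind(own, amb) else cbind(amb, own)
    }
    ca <- draw(n_a, mean_a, mean_b, TRUE)
    cb <- draw(n_b, mean_b, mean_a, FALSE)
    counts <- rbind(ca, cb)
    species <- c(rep("A", n_a), rep("B", n_b))
    rownames(counts) <- sprintf("%s-%04d", species, c(seq_len(n_a), seq_len(n_b)))

    n_d <- round(doublet_rate * (n_a + n_b))
    truth <- tibble(barcode = rownames(counts), species = species,
                    is_doublet = FALSE, is_cross_species = FALSE)
    if (n_d > 0) {
      i1 <- sample.int(nrow(counts), n_d, replace = TRUE)
      i2 <- sample.int(nrow(counts), n_d, replace = TRUE)
      dbl <- counts[i1, , drop = FALSE] + counts[i2, , drop = FALSE]
      rownames(dbl) <- sprintf("DBL-%04d", seq_len(n_d))
      cross <- species[i1] != species[i2]
      truth <- bind_rows(truth, tibble(
        barcode = rownames(dbl),
        species = paste(species[i1], species[i2], sep = "+"),
        is_doublet = TRUE,
        is_cross_species = cross
      ))
      counts <- rbind(counts, dbl)
    }
    colnames(counts) <- genes
    structure(
      list(
        counts = methods::as(Matrix(counts, sparse = TRUE), "generalMatrix"),
        truth = truth,
        planted_rate = if (nrow(truth)) sum(truth$is_doublet) / nrow(truth) else 0
      ),
      class = "barnyard_sim"
    )
  })
}

#' Normalization scale matching a partial simulated transcriptome
#'
#' The counts-per-10,000 convention presumes a full (~20,000-gene) human
#' transcriptome. A simulation of `n_genes` genes concentrates the same
#' library into fewer genes, which would inflate normalized expression and
#' with it any absolute score threshold. Scaling the target total by the
#' simulated transcriptome fraction keeps normalized magnitudes on the
#' real-data scale.
#'
#' @param n_genes Number of simulated genes.
#' @param transcriptome_genes Size of the full transcriptome the simulation
#'   stands in for (default 20,000).
#' @return The per-cell target total for [normalize_counts()].
#' @export
sim_scale_factor <- function(n_genes, transcriptome_genes = 20000) {
  1e4 * n_genes / transcriptome_genes
}
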