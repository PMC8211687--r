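#' Per-patient composition trading T cells for macrophages
#'
#' Builds a patients-by-types cell-count matrix in which the T-cell share of
#' the T + TAM pool rises across patients while the TAM share falls (slope
#' -1 on shares), with multiplicative Gaussian noise on both counts. Used to
#' plant the inverse macrophage/T-cell composition pattern for correlation
#' analyses.
#'
#' @param n_patients Number of patients.
#' @param cells_per_type Named base counts per type (defaults to the
#'   [sim_config()] default).
#' @param t_types Types pooled as "T cells".
#' @param tam_type The macrophage type.
#' @param span T-cell share of the pool ranges over `0.5 +/- span/2`.
#' @param noise Multiplicative noise SD (default 0.05).
#' @param seed Integer seed.
#' @return An integer matrix, `n_patients` rows, one column per type.
#' @export
tradeoff_composition <- function(n_patients = 8L,
                                 cells_per_type = formals(sim_config)$cells_per_type,
                                 t_types = c("CD8T", "CD4T", "Treg"),
                                 tam_type = "TAM", span = 0.5, noise = 0.05,
                                 seed = 19L) {
  base <- eval(cells_per_type)
  pool <- sum(base[t_types]) + base[[tam_type]]
  f <- seq(0.5 - span / 2, 0.5 + span / 2, length.out = n_patients)
  with_seed(seed, {
    t_i <- pmax(3L, round(pool * f * (1 + stats::rnorm(n_patients, 0, noise))))
    tam_i <- pmax(1L, round(pool * (1 - f) * (1 + stats::rnorm(n_patients, 0, noise))))
  })
  m <- matrix(rep(base, each = n_patients), nrow = n_patients,
              dimnames = list(NULL, names(base)))
  t_share <- base[t_types] / sum(base[t_types])
  for (i in seq_len(n_patients)) {
    split <- pmax(1L, round(t_i[i] * t_share))
    m[i, t_types] <- split
    m[i, tam_type] <- tam_i[i]
  }
  storage.mode(m) <- "integer"
  m
}

# Decoy ligand-receptor axes drawn deterministically from the generic gene
# pool, interleaved so ligand and receptor never coincide.
decoy_axes <- function(n, offset = 100L) {
  idx <- offset + seq_len(2L * n)
  tibble(
    axis = paste0("null", seq_len(n)),
    ligand = sprintf("G%04d", idx[seq(1L, 2L * n, by = 2L)]),
    receptor = sprintf("G%04d", idx[seq(2L, 2L * n, by = 2L)]),
    category = "generic"
  )
}

#' Default end-to-end demonstration configuration
#'
#' A full-pipeline configuration on the default simulation: patient
#' compositions trade macrophages for T cells, tumor cells carry the LCSC
#' marker panel as their identity program, one checkpoint axis is planted,
#' and per-patient CNV segments distinguish tumor clones.
#'
#' @param seed Global pipeline seed.
#' @return A `run_config` list accepted by [run_pipeline()].
#' @export
demo_config <- function(seed = 42L) {
  types <- eval(formals(sim_config)$cells_per_type)
  markers <- lapply(setNames(names(types), names(types)), function(t) {
    paste0(t, ".mk", 1:5)
  })
  markers$Tumor <- lcsc_panel()
  cfg <- list(
    seed = seed,
    sim = sim_config(
      cells_per_type = tradeoff_composition(seed = seed),
      markers = markers
    ),
    qc = list(min_genes = 200L, max_mito = 0.2, min_cells_per_gene = 3L),
    hvg = list(n_top = 200L),
    annotate = list(),
    cnv = list(window = 100L, step = 1L, cap = 3, k = 8L,
               reference_type = "Hepatocyte"),
    checkpoint = list(B = 200L, mode = "strict",
                      senders = c("Tumor", "TAM"),
                      receivers = c("CD8T", "CD4T", "Treg", "NK"),
                      n_decoys = 10L),
    interactome = list(score_threshold = 0.5, q_threshold = 0.05,
                       cell_types = c("Tumor", "TAM", "CD8T", "CD4T",
                                      "Treg", "NK", "B"),
                       n_decoys = 30L),
    markers = list(k = 4L),
    correlate = list(type_a = "T", type_b = "TAM")
  )
  class(cfg) <- "run_config"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' Stage parameter blocks are read as lists; the `sim` block is passed to
#' [sim_config()].
#'
#' @param path YAML file.
#' @return A `run_config` list.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- demo_config(seed = raw$seed %||% 42L)
  for (nm in setdiff(names(raw), c("seed", "sim"))) {
    if (!nm %in% names(cfg)) {
      abort_config(paste0("unknown config block: ", nm))
    }
    cfg[[nm]] <- modifyList(cfg[[nm]], raw[[nm]])
  }
  if (!is.null(raw$sim)) {
    cfg$sim <- do.call(sim_config, raw$sim)
  }
  validate_run_config(cfg)
  cfg
}

validate_run_config <- function(config) {
  allowed <- c("seed", "sim", "qc", "hvg", "annotate", "cnv", "checkpoint",
               "interactome", "markers", "correlate")
  unknown <- setdiff(names(config), allowed)
  if (length(unknown)) {
    abort_config(paste0("unknown config block(s): ",
                        paste(unknown, collapse = ", ")))
  }
  missing <- setdiff(allowed, names(config))
  if (length(missing)) {
    abort_config(paste0("missing config block(s): ",
                        paste(missing, collapse = ", ")))
  }
  stage_keys <- list(
    qc = c("min_genes", "max_mito", "min_cells_per_gene"),
    hvg = c("n_top"),
    annotate = c("panel"),
    cnv = c("window", "step", "cap", "k", "reference_type"),
    checkpoint = c("B", "mode", "senders", "receivers", "n_decoys", "pairs"),
    interactome = c("score_threshold", "q_threshold", "cell_types",
                    "n_decoys", "pairs"),
    markers = c("k", "panel"),
    correlate = c("type_a", "type_b")
  )
  for (st in names(stage_keys)) {
    bad <- setdiff(names(config[[st]]), stage_keys[[st]])
    if (length(bad)) {
      abort_config(paste0("unknown key(s) in '", st, "' block: ",
                          paste(bad, collapse = ", ")))
    }
  }
  validate_sim_config(config$sim)
  qc <- config$qc
  if (qc$min_genes < 0) abort_config("qc: min_genes must be >= 0")
  if (qc$max_mito < 0 || qc$max_mito > 1) {
    abort_config("qc: max_mito must lie in [0, 1]")
  }
  if (config$hvg$n_top < 1) abort_config("hvg: n_top must be >= 1")
  if (config$cnv$window < 1) abort_config("cnv: window must be >= 1")
  if (config$checkpoint$B < 1) abort_config("checkpoint: B must be >= 1")
  if (config$markers$k < 1) abort_config("markers: k must be >= 1")
  invisible(config)
}

#' Run the full demonstration pipeline
#'
#' Runs simulate -> qc -> annotate -> cnv -> checkpoint -> interactome ->
#' markers -> correlate in dependency order, writing each stage's TSV
#' outputs under `outdir` together with a machine-readable JSON run manifest
#' (stage, parameters, sub-seed, output file MD5 hashes). Identical config +
#' seed give byte-identical outputs. Each stage draws from its own sub-seed
#' derived from the global seed and the stage name, so adding a stage never
#' shifts another stage's randomness. On error a `FAILED` marker naming the
#' stage is left next to any partial outputs.
#'
#' @param config A `run_config`, e.g. [demo_config()].
#' @param outdir Output directory (created).
#' @param seed Optional override of `config$seed`.
#' @return Invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(config = demo_config(), outdir, seed = NULL) {
  validate_run_config(config)
  seed <- seed %||% config$seed
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(seed = seed, stages = list())
  current_stage <- "init"
  record <- function(stage, params, files) {
    manifest$stages[[stage]] <<- list(
      stage = stage, params = params, seed = stage_seed(seed, stage),
      outputs = {
        f <- unlist(files)
        as.list(setNames(unname(tools::md5sum(f)),
                         sub(paste0("^", outdir, "/?"), "", f)))
      }
    )
  }
  out <- function(name) file.path(outdir, name)

  res <- tryCatch({
    ## simulate ------------------------------------------------------------
    current_stage <- "simulate"
    sim_cfg <- config$sim
    sim_cfg$seed <- stage_seed(seed, "simulate")
    sim <- simulate_tme(sim_cfg)
    f_counts <- write_count_matrix(sim$counts, out("counts"))
    f_truth <- write_table(sim$truth, out("truth.tsv"), key = "barcode")
    pos_bed <- sim$gene_positions[, c("chrom", "start", "end", "gene", "strand")]
    readr::write_tsv(pos_bed, out("genes.bed"), col_names = FALSE,
                     progress = FALSE)
    record("simulate", list(n_patients = sim_cfg$n_patients,
                            n_genes = sim_cfg$n_genes,
                            doublet_rate = sim_cfg$doublet_rate),
           c(f_counts, f_truth, out("genes.bed")))

    ## qc ------------------------------------------------------------------
    current_stage <- "qc"
    ann0 <- sim$truth[, c("barcode", "patient")]
    names(ann0)[2] <- "sample"
    qc <- qc_filter(sim$counts, ann0,
                    min_genes = config$qc$min_genes,
                    max_mito = config$qc$max_mito,
                    min_cells_per_gene = config$qc$min_cells_per_gene,
                    mito = sim$mito_genes)
    f_qc <- write_table(qc$annotation, out("qc_annotation.tsv"),
                        key = "barcode")
    record("qc", config$qc, f_qc)

    ## annotate ------------------------------------------------------------
    current_stage <- "annotate"
    expr <- normalize_counts(qc$counts,
                             scale = sim_scale_factor(config$sim$n_genes))
    hvg <- select_hvg(expr, n_top = config$hvg$n_top)
    f_hvg <- write_table(hvg, out("hvg.tsv"))
    panel <- config$annotate$panel %||% sim$markers
    ann <- assign_cell_types(expr, panel)
    ann <- left_join(ann, qc$annotation[, c("barcode", "sample")],
                     by = "barcode")
    f_ann <- write_table(ann, out("cell_types.tsv"), key = "barcode")
    record("annotate", list(n_top = config$hvg$n_top,
                            types = names(panel)), c(f_hvg, f_ann))

    ## cnv -----------------------------------------------------------------
    current_stage <- "cnv"
    ref_ids <- ann$barcode[ann$cell_type == config$cnv$reference_type]
    tum_ids <- ann$barcode[ann$cell_type == "Tumor"]
    cells <- c(tum_ids, ref_ids)
    rel <- relative_expression(expr[cells, , drop = FALSE], ref_ids,
                               cap = config$cnv$cap)
    prof <- cnv_moving_average(rel, sim$gene_positions,
                               window = config$cnv$window,
                               step = config$cnv$step,
                               reference_ids = ref_ids)
    prof <- center_on_reference(prof)
    grouping <- cluster_cnv_groups(
      structure(list(scores = prof$scores[tum_ids, , drop = FALSE],
                     window_map = prof$window_map), class = "cnv_profile"),
      k = config$cnv$k
    )
    f_map <- write_table(prof$window_map, out("cnv_windows.tsv"))
    f_grp <- write_table(grouping$groups, out("cnv_groups.tsv"),
                         key = "barcode")
    scores_tbl <- as_tibble(prof$scores, rownames = "barcode")
    f_sc <- write_table(scores_tbl, out("cnv_scores.tsv"), key = "barcode")
    as_newick(grouping, out("cnv_tree.nwk"))
    record("cnv", config$cnv[c("window", "step", "cap", "k")],
           c(f_map, f_grp, f_sc, out("cnv_tree.nwk")))

    ## checkpoint ----------------------------------------------------------
    current_stage <- "checkpoint"
    cp_pairs <- config$checkpoint$pairs %||% bind_rows(
      mutate(sim$axes[, c("ligand", "receptor")],
             axis = paste(.data$ligand, .data$receptor, sep = "-"),
             category = "co-inhibitory"),
      decoy_axes(config$checkpoint$n_decoys %||% 10L)
    )
    cp <- checkpoint_panel(expr, ann, cp_pairs,
                           sender_types = config$checkpoint$senders,
                           receiver_types = config$checkpoint$receivers,
                           B = config$checkpoint$B,
                           seed = stage_seed(seed, "checkpoint"),
                           mode = config$checkpoint$mode)
    f_cp <- write_table(cp, out("checkpoint.tsv"),
                        key = c("axis", "sender", "receiver"))
    record("checkpoint", config$checkpoint[c("B", "mode")], f_cp)

    ## interactome ---------------------------------------------------------
    current_stage <- "interactome"
    it_pairs <- config$interactome$pairs %||% bind_rows(
      mutate(sim$axes[, c("ligand", "receptor")],
             axis = paste(.data$ligand, .data$receptor, sep = "-"),
             category = "co-inhibitory"),
      decoy_axes(config$interactome$n_decoys %||% 30L, offset = 300L)
    )
    it <- interactome(expr, ann, it_pairs,
                      cell_types = config$interactome$cell_types,
                      score_threshold = config$interactome$score_threshold,
                      q_threshold = config$interactome$q_threshold)
    f_it <- write_table(it$summary, out("interactome_summary.tsv"))
    f_its <- write_table(it$scores, out("interactome_scores.tsv"),
                         key = c("axis", "sender", "receiver"))
    record("interactome",
           config$interactome[c("score_threshold", "q_threshold")],
           c(f_it, f_its))

    ## markers (LCSC stratification) ---------------------------------------
    current_stage <- "markers"
    panel_lcsc <- config$markers$panel %||% lcsc_panel()
    lg <- lcsc_groups(expr[tum_ids, , drop = FALSE], panel = panel_lcsc,
                      k = config$markers$k,
                      sample = setNames(ann$sample, ann$barcode)[tum_ids])
    f_lg <- write_table(lg$groups, out("lcsc_groups.tsv"), key = "barcode")
    f_ct <- write_table(lg$contingency, out("lcsc_contingency.tsv"),
                        key = "sample")
    as_newick(lg, out("lcsc_tree.nwk"))
    record("markers", config$markers["k"],
           c(f_lg, f_ct, out("lcsc_tree.nwk")))

    ## correlate -----------------------------------------------------------
    current_stage <- "correlate"
    ann_t <- mutate(ann, cell_type = ifelse(
      .data$cell_type %in% c("CD8T", "CD4T", "Treg"), "T", .data$cell_type))
    comp <- composition(ann_t)
    corr <- proportion_correlation(comp, config$correlate$type_a,
                                   config$correlate$type_b)
    f_comp <- write_table(comp, out("composition.tsv"),
                          key = c("sample", "cell_type", "within"))
    f_corr <- write_table(corr, out("correlation.tsv"))
    record("correlate", config$correlate, c(f_comp, f_corr))

    jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                         pretty = TRUE, digits = NA)
    list(sim = sim, qc = qc, expr = expr, annotation = ann, hvg = hvg,
         cnv_profile = prof, cnv_grouping = grouping, checkpoint = cp,
         interactome = it, lcsc = lg, composition = comp, correlation = corr,
         manifest = manifest)
  }, error = function(e) {
    writeLines(paste0("FAILED at stage: ", current_stage, "\n",
                      conditionMessage(e)), out("FAILED"))
    abort(paste0("pipeline failed at stage '", current_stage, "': ",
                 conditionMessage(e)), parent = e)
  })
  invisible(res)
}
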