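test_that("relative expression centers on the reference and clamps", {
  ex <- toy_matrix(c(1, 1, 11, 2, 2, 2), 3, 2)
  rel <- relative_expression(ex, reference_ids = "C01", cap = 3)
  expect_equal(unname(rel["C01", ]), c(0, 0))
  expect_equal(unname(rel["C02", "G01"]), 0)
  expect_equal(unname(rel["C03", "G01"]), 3)   # +10 clamped to cap
  expect_equal(unname(rel["C02", "G02"]), 0)

  # toy oracle: output equals input minus reference row (within the cap)
  ex2 <- toy_matrix(c(0.5, 1, 2, 1.5, 0.2, 2.2), 3, 2)
  rel2 <- relative_expression(ex2, "C01", cap = 3)
  expect_equal(unname(rel2), unname(sweep(as.matrix(ex2), 2,
                                          as.numeric(ex2["C01", ]))))

  expect_error(relative_expression(ex, character(0)),
               class = "tmescope_config_error")
  expect_error(relative_expression(ex, "nope"),
               class = "tmescope_config_error")
})

test_that("moving average reproduces hand-computed window means", {
  ex <- toy_matrix(1:5, 1, 5, barcodes = "c1")
  pos <- tibble::tibble(chrom = "chr1", start = (0:4) * 1e4,
                        end = (0:4) * 1e4 + 1000,
                        gene = sprintf("G%02d", 1:5), strand = "+")
  prof <- cnv_moving_average(as.matrix(ex), pos, window = 3, step = 1)
  expect_equal(unname(prof$scores[1, ]), c(2, 3, 4))
  expect_equal(prof$window_map$start_gene, c("G01", "G02", "G03"))

  prof1 <- cnv_moving_average(as.matrix(ex), pos, window = 1)
  expect_equal(unname(prof1$scores[1, ]), 1:5)
})

test_that("moving average equals a brute-force window loop", {
  set.seed(11)
  n_genes <- 200
  n_cells <- 20
  rel <- matrix(rnorm(n_cells * n_genes), n_cells, n_genes,
                dimnames = list(sprintf("c%02d", 1:n_cells),
                                sprintf("G%03d", 1:n_genes)))
  pos <- tibble::tibble(chrom = "chr1", start = (0:(n_genes - 1)) * 1e4,
                        end = (0:(n_genes - 1)) * 1e4 + 1000,
                        gene = sprintf("G%03d", 1:n_genes), strand = "+")
  w <- 100
  prof <- cnv_moving_average(rel, pos, window = w, step = 1)
  brute <- sapply(1:(n_genes - w + 1), function(s) {
    rowMeans(rel[, s:(s + w - 1)])
  })
  expect_lt(max(abs(prof$scores - brute)), 1e-12)
})

test_that("short chromosomes yield one flagged truncated window", {
  rel <- matrix(1:8, 2, 4, dimnames = list(c("a", "b"),
                                           c("g1", "g2", "g3", "g4")))
  pos <- tibble::tibble(chrom = c("chr1", "chr1", "chr1", "chr2"),
                        start = c(0, 1e4, 2e4, 0),
                        end = c(1000, 1.1e4, 2.1e4, 1000),
                        gene = c("g1", "g2", "g3", "g4"), strand = "+")
  prof <- cnv_moving_average(rel, pos, window = 2)
  wm <- prof$window_map
  expect_equal(sum(wm$truncated), 1L)
  expect_equal(wm$chrom[wm$truncated], "chr2")
  expect_equal(wm$n_genes[wm$truncated], 1L)
  # truncated window score = mean over all that chromosome's genes
  expect_equal(unname(prof$scores[, ncol(prof$scores)]),
               unname(rowMeans(rel[, "g4", drop = FALSE])))
})

test_that("moving average commutes with cell permutation; scores bounded by members", {
  set.seed(12)
  rel <- matrix(rnorm(10 * 30), 10, 30,
                dimnames = list(sprintf("c%02d", 1:10),
                                sprintf("G%03d", 1:30)))
  pos <- tibble::tibble(chrom = "chr1", start = (0:29) * 1e4,
                        end = (0:29) * 1e4 + 1000,
                        gene = sprintf("G%03d", 1:30), strand = "+")
  p1 <- cnv_moving_average(rel, pos, window = 7)
  perm <- sample(10)
  p2 <- cnv_moving_average(rel[perm, ], pos, window = 7)
  expect_equal(p1$scores[rownames(p2$scores), ], p2$scores)
  for (j in seq_len(ncol(p1$scores))) {
    members <- rel[, j:(j + 6)]
    expect_true(all(p1$scores[, j] >= apply(members, 1, min) - 1e-12))
    expect_true(all(p1$scores[, j] <= apply(members, 1, max) + 1e-12))
  }
})

test_that("reference centering zeroes the reference mean profile", {
  set.seed(13)
  rel <- matrix(rnorm(6 * 20), 6, 20,
                dimnames = list(sprintf("c%d", 1:6),
                                sprintf("G%03d", 1:20)))
  pos <- tibble::tibble(chrom = "chr1", start = (0:19) * 1e4,
                        end = (0:19) * 1e4 + 1000,
                        gene = sprintf("G%03d", 1:20), strand = "+")
  prof <- cnv_moving_average(rel, pos, window = 5,
                             reference_ids = c("c1", "c2"))
  cen <- center_on_reference(prof)
  expect_equal(unname(colMeans(cen$scores[c("c1", "c2"), ])),
               rep(0, ncol(cen$scores)))

  # reference-only input becomes identically zero on average; adding a
  # constant to every cell leaves the centered output unchanged
  shifted <- prof
  shifted$scores <- prof$scores + 0.7
  expect_equal(center_on_reference(shifted)$scores, cen$scores)
})

test_that("planted segments are recovered in sign and patients separate at k = 2", {
  cfg <- sim_config(
    seed = 5, n_patients = 2,
    cells_per_type = c(Tumor = 60L, Hepatocyte = 40L),
    doublet_rate = 0,
    cnv_segments = tibble::tibble(
      patient = c(1L, 1L, 2L, 2L),
      chrom = c("chr1", "chr2", "chr3", "chr4"),
      start_gene = 26L, end_gene = 175L,
      log2fc = c(0.5, -0.5, 1, -1)
    )
  )
  sim <- simulate_tme(cfg)
  ex <- sim_expr(sim)
  truth <- sim$truth
  ref <- truth$barcode[truth$cell_type == "Hepatocyte"]
  tum <- truth$barcode[truth$cell_type == "Tumor"]
  rel <- relative_expression(ex[c(tum, ref), ], ref)
  prof <- suppressMessages(
    cnv_moving_average(rel, sim$gene_positions, window = 100,
                       reference_ids = ref)
  )
  prof <- center_on_reference(prof)
  expect_gte(cnv_sign_recovery(prof, sim), 0.95)

  tum_prof <- prof
  tum_prof$scores <- prof$scores[tum, ]
  grp <- cluster_cnv_groups(tum_prof, k = 2)
  expect_gte(ari(grp$groups$group,
                 truth$patient[match(grp$groups$barcode, truth$barcode)]),
             0.9)
})

test_that("a no-CNV simulation produces no spurious CNV signal", {
  cfg <- sim_config(
    seed = 23, n_patients = 2,
    cells_per_type = c(Tumor = 40L, Hepatocyte = 40L),
    doublet_rate = 0,
    cnv_segments = tibble::tibble(patient = integer(), chrom = character(),
                                  start_gene = integer(),
                                  end_gene = integer(), log2fc = numeric())
  )
  sim <- simulate_tme(cfg)
  ex <- sim_expr(sim)
  truth <- sim$truth
  ref <- truth$barcode[truth$cell_type == "Hepatocyte"]
  tum <- truth$barcode[truth$cell_type == "Tumor"]
  rel <- relative_expression(ex[c(tum, ref), ], ref)
  prof <- center_on_reference(
    cnv_moving_average(rel, sim$gene_positions, window = 100,
                       reference_ids = ref)
  )
  ref_sd <- apply(prof$scores[ref, ], 2, sd)
  inside <- abs(prof$scores[tum, ]) <= 3 * rep(ref_sd, each = length(tum))
  # evaluated on the CNV-interpretable chromosomes: the last chromosome
  # hosts the planted identity programs, whose tumor-vs-hepatocyte
  # expression differences are real but are not copy-number signal
  eligible <- which(prof$window_map$chrom != "chr5")
  expect_gte(mean(inside[, eligible]), 0.99)
  # and no spurious segment: >= 5 consecutive outlying windows in < 10% of cells
  run_max <- apply(!inside[, eligible], 1, function(x) {
    r <- rle(x)
    m <- r$lengths[r$values]
    if (length(m)) max(m) else 0L
  })
  expect_lt(mean(run_max >= 5), 0.10)
})

test_that("clustering edge cases: singletons, duplicates, k bounds", {
  sc <- matrix(c(0, 0, 5, 5, 9, 9), 3, 2, byrow = TRUE,
               dimnames = list(c("a", "b", "c"), c("w1", "w2")))
  prof <- structure(list(scores = sc), class = "cnv_profile")
  g <- cluster_cnv_groups(prof, k = 3)
  expect_equal(sort(unique(g$groups$group)), 1:3)
  expect_error(cluster_cnv_groups(prof, k = 4),
               class = "tmescope_config_error")
  expect_error(cluster_cnv_groups(prof),
               class = "tmescope_config_error")

  dup <- structure(list(scores = sc[c(1, 1, 2), ]), class = "cnv_profile")
  rownames(dup$scores) <- c("a", "a2", "b")
  gd <- cluster_cnv_groups(dup, k = 2)
  lab <- setNames(gd$groups$group, gd$groups$barcode)
  expect_equal(lab[["a"]], lab[["a2"]])
  expect_equal(min(gd$hclust$height), 0)
})

test_that("dendrograms round-trip through Newick", {
  set.seed(14)
  sc <- matrix(rnorm(12), 6, 2,
               dimnames = list(paste0("cell", 1:6), c("w1", "w2")))
  prof <- structure(list(scores = sc), class = "cnv_profile")
  g <- cluster_cnv_groups(prof, k = 2)
  path <- withr::local_tempfile(fileext = ".nwk")
  as_newick(g, path)
  tr <- ape::read.tree(path)
  expect_setequal(tr$tip.label, paste0("cell", 1:6))
  expect_true(ape::all.equal.phylo(tr, ape::as.phylo(g$hclust),
                                   use.edge.length = FALSE))
})
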