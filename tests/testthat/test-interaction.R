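make_expr <- function(lig_vals, rec_vals) {
  n_s <- length(lig_vals)
  n_r <- length(rec_vals)
  ex <- matrix(0, n_s + n_r, 2,
               dimnames = list(
                 c(sprintf("s%02d", seq_len(n_s)),
                   sprintf("r%02d", seq_len(n_r))),
                 c("LIG", "REC")
               ))
  ex[seq_len(n_s), "LIG"] <- lig_vals
  ex[n_s + seq_len(n_r), "REC"] <- rec_vals
  ann <- tibble::tibble(barcode = rownames(ex),
                        cell_type = rep(c("APC", "Tcell"), c(n_s, n_r)))
  list(expr = ex, ann = ann)
}

test_that("interaction score is the product of group means", {
  f <- make_expr(c(1, 2, 3), c(0, 4))
  s <- interaction_score(f$expr, f$ann, "LIG", "REC", "APC", "Tcell")
  expect_equal(s, 4)

  expect_warning(
    s0 <- interaction_score(f$expr, f$ann, "ABSENT", "REC", "APC", "Tcell"),
    "absent"
  )
  expect_equal(s0, 0)
  expect_error(interaction_score(f$expr, f$ann, "LIG", "REC", "APC", "NK"),
               "NK")
})

test_that("interaction score equals a two-loop brute force and is bilinear", {
  set.seed(13)
  n <- 50
  ex <- matrix(runif(n * 4), n, 4,
               dimnames = list(sprintf("c%02d", 1:n),
                               c("LIG", "REC", "X", "Y")))
  ann <- tibble::tibble(barcode = rownames(ex),
                        cell_type = sample(c("APC", "Tcell", "Other"), n,
                                           replace = TRUE))
  s <- interaction_score(ex, ann, "LIG", "REC", "APC", "Tcell")
  acc_l <- 0; n_l <- 0; acc_r <- 0; n_r <- 0
  for (i in seq_len(n)) {
    if (ann$cell_type[i] == "APC") { acc_l <- acc_l + ex[i, "LIG"]; n_l <- n_l + 1 }
    if (ann$cell_type[i] == "Tcell") { acc_r <- acc_r + ex[i, "REC"]; n_r <- n_r + 1 }
  }
  expect_lt(abs(s - (acc_l / n_l) * (acc_r / n_r)), 1e-12)

  ex2 <- ex
  ex2[ann$cell_type == "APC", "LIG"] <- 3 * ex2[ann$cell_type == "APC", "LIG"]
  s2 <- interaction_score(ex2, ann, "LIG", "REC", "APC", "Tcell")
  expect_equal(s2, 3 * s)
})

test_that("degenerate ties give p = 0 (strict) and 1 (plus_one)", {
  ex <- matrix(1, 6, 2, dimnames = list(sprintf("c%d", 1:6), c("LIG", "REC")))
  ann <- tibble::tibble(barcode = rownames(ex),
                        cell_type = rep(c("APC", "Tcell"), each = 3))
  ps <- permutation_p(ex, ann, "LIG", "REC", "APC", "Tcell", B = 50,
                      seed = 1, mode = "strict")
  expect_equal(ps$p, 0)
  pp <- permutation_p(ex, ann, "LIG", "REC", "APC", "Tcell", B = 50,
                      seed = 1, mode = "plus_one")
  expect_equal(pp$p, 1)
  expect_error(permutation_p(ex, ann, "LIG", "REC", "APC", "Tcell", B = 0),
               class = "tmescope_config_error")
})

test_that("exhaustive permutation p matches independent enumeration on 2+2 cells", {
  f <- make_expr(c(1, 5), c(2, 3))
  res <- permutation_p(f$expr, f$ann, "LIG", "REC", "APC", "Tcell",
                       scope = "pair", exhaustive = TRUE)
  # independent oracle: enumerate every assignment of 2 sender labels to 4 cells
  lig <- f$expr[, "LIG"]; rec <- f$expr[, "REC"]
  combos <- combn(4, 2)
  s_all <- apply(combos, 2, function(idx) {
    mean(lig[idx]) * mean(rec[setdiff(1:4, idx)])
  })
  s_obs <- mean(lig[1:2]) * mean(rec[3:4])
  expect_equal(res$n_perm, 6L)
  expect_equal(res$score, s_obs)
  expect_lt(abs(res$p - mean(s_all > s_obs)), 1e-12)

  # plus_one exhaustive p is super-uniform over thresholds on this instance
  resp <- permutation_p(f$expr, f$ann, "LIG", "REC", "APC", "Tcell",
                        scope = "pair", exhaustive = TRUE, mode = "plus_one")
  expect_lt(abs(resp$p - (sum(s_all >= s_obs) + 1) / 7), 1e-12)
})

test_that("sampled permutation p converges to the exhaustive value", {
  f <- make_expr(c(1, 5, 2), c(2, 3, 7))
  exact <- permutation_p(f$expr, f$ann, "LIG", "REC", "APC", "Tcell",
                         scope = "pair", exhaustive = TRUE)
  sampled <- permutation_p(f$expr, f$ann, "LIG", "REC", "APC", "Tcell",
                           scope = "pair", B = 4000, seed = 99)
  expect_lt(abs(sampled$p - exact$p), 0.05)
})

test_that("seeded permutations are reproducible and cell-order invariant", {
  sim <- simulate_tme(small_sim_config(seed = 8))
  ex <- sim_expr(sim)
  ann <- sim$truth
  pairs <- tibble::tibble(axis = "NECTIN2-TIGIT", ligand = "NECTIN2",
                          receptor = "TIGIT")
  r1 <- checkpoint_panel(ex, ann, pairs, "Tumor", "CD8T", B = 100, seed = 5)
  r2 <- checkpoint_panel(ex, ann, pairs, "Tumor", "CD8T", B = 100, seed = 5)
  expect_equal(r1, r2)
  perm <- sample(nrow(ex))
  r3 <- checkpoint_panel(ex[perm, ], ann[sample(nrow(ann)), ], pairs,
                         "Tumor", "CD8T", B = 100, seed = 5)
  expect_equal(as.data.frame(r1), as.data.frame(r3))
})

test_that("a planted checkpoint axis tops the panel with small empirical p", {
  sim <- simulate_tme(sim_config(seed = 5))
  ex <- sim_expr(sim)
  ann <- sim$truth
  pairs <- dplyr::bind_rows(
    tibble::tibble(axis = "NECTIN2-TIGIT", ligand = "NECTIN2",
                   receptor = "TIGIT", category = "co-inhibitory"),
    tmescope:::decoy_axes(10)
  )
  cp <- checkpoint_panel(ex, ann, pairs,
                         sender_types = c("Tumor", "TAM"),
                         receiver_types = c("CD8T", "CD4T", "Treg", "NK"),
                         B = 1000, seed = 5)
  dir <- cp[cp$sender == "Tumor" & cp$receiver == "CD8T", ]
  expect_equal(dir$axis[which.max(dir$score)], "NECTIN2-TIGIT")
  expect_lte(dir$p[dir$axis == "NECTIN2-TIGIT"], 0.01)

  single <- checkpoint_panel(ex, ann, pairs[1, ], "Tumor", "CD8T",
                             B = 50, seed = 1)
  expect_equal(nrow(single), 1L)
})

test_that("wilcoxon helper matches full sign-assignment enumeration", {
  # exact textbook case: scores (0.6, 0.7, 0.8), one-sided
  expect_equal(tmescope:::wilcoxon_signed_p(c(0.6, 0.7, 0.8)), 0.125)

  # independent oracle: enumerate all 2^n signed-rank sums
  enum_p <- function(x) {
    x <- x[x != 0]
    n <- length(x)
    r <- rank(abs(x))
    w_obs <- sum(r[x > 0])
    signs <- expand.grid(rep(list(c(0, 1)), n))
    w_all <- as.matrix(signs) %*% r
    mean(w_all >= w_obs)
  }
  set.seed(17)
  for (n in c(4, 7, 10)) {
    x <- round(rnorm(n), 3)
    x <- x[!duplicated(abs(x))]
    expect_equal(tmescope:::wilcoxon_signed_p(x), enum_p(x),
                 tolerance = 1e-12)
  }
  # zeros are dropped; an all-zero sample is evidence-free
  expect_equal(tmescope:::wilcoxon_signed_p(c(0, 0, 0)), 1)
  expect_equal(tmescope:::wilcoxon_signed_p(c(0, 0.6, 0.7, 0.8)), 0.125)
})

test_that("storey q-values reduce to BH at pi0 = 1 and stay monotone", {
  expect_equal(as.numeric(storey_qvalue(0.04, pi0 = 1)), 0.04)
  expect_equal(as.numeric(storey_qvalue(rep(1, 5))), rep(1, 5))
  expect_error(storey_qvalue(c(0.5, 1.2)), class = "tmescope_config_error")

  set.seed(17)
  p <- runif(20)
  q <- as.numeric(storey_qvalue(p, pi0 = 1))
  expect_equal(q, p.adjust(p, method = "BH"))

  q2 <- storey_qvalue(p)
  expect_true(all(diff(as.numeric(q2)[order(p)]) >= -1e-12))
  expect_true(attr(q2, "pi0") > 0 && attr(q2, "pi0") <= 1)
  # estimated-pi0 q-values shrink BH by exactly pi0 before monotonization
  expect_true(all(as.numeric(q2) <= q + 1e-12))
})

test_that("interactome flags a planted broad pair and spares null pairs", {
  cfg <- sim_config(
    seed = 1,
    planted_axes = tibble::tibble(ligand = "LIGX", receptor = "RECX",
                                  sender = "*", receiver = "*", fold = 8)
  )
  sim <- simulate_tme(cfg)
  ex <- sim_expr(sim)
  pairs <- dplyr::bind_rows(
    tibble::tibble(axis = "LIGX-RECX", ligand = "LIGX", receptor = "RECX",
                   category = "generic"),
    tmescope:::decoy_axes(30, offset = 300)
  )
  it <- interactome(ex, sim$truth, pairs,
                    cell_types = c("Tumor", "TAM", "CD8T", "CD4T", "Treg",
                                   "NK", "B"))
  sm <- it$summary
  expect_true(sm$significant[sm$axis == "LIGX-RECX"])
  expect_gte(mean(!sm$significant[sm$axis != "LIGX-RECX"]), 0.9)
  # significance call matches its definition
  expect_equal(sm$significant,
               sm$median_score > 0.5 & sm$storey_q < 0.05)
  expect_equal(nrow(it$scores), nrow(pairs) * 7 * 6)

  # invariant to pair-table row order
  it2 <- interactome(ex, sim$truth, pairs[rev(seq_len(nrow(pairs))), ],
                     cell_types = c("Tumor", "TAM", "CD8T", "CD4T", "Treg",
                                    "NK", "B"))
  expect_equal(as.data.frame(it2$summary[rev(seq_len(nrow(pairs))), ]),
               as.data.frame(sm), ignore_attr = TRUE)
})

test_that("interactome handles absent genes as an all-zero, p = 1 path", {
  sim <- simulate_tme(small_sim_config(seed = 2))
  ex <- sim_expr(sim)
  pairs <- tibble::tibble(axis = c("gone", "real"),
                          ligand = c("NOPE1", "NECTIN2"),
                          receptor = c("NOPE2", "TIGIT"),
                          category = "generic")
  it <- suppressWarnings(
    interactome(ex, sim$truth, pairs,
                cell_types = c("Tumor", "CD8T", "TAM"))
  )
  gone <- it$summary[it$summary$axis == "gone", ]
  expect_equal(gone$median_score, 0)
  expect_equal(gone$wilcoxon_p, 1)
  expect_false(gone$significant)
})

test_that("tidy and glance summarize interactome results", {
  sim <- simulate_tme(small_sim_config(seed = 2))
  ex <- sim_expr(sim)
  pairs <- tibble::tibble(axis = "NECTIN2-TIGIT", ligand = "NECTIN2",
                          receptor = "TIGIT", category = "co-inhibitory")
  it <- interactome(ex, sim$truth, pairs,
                    cell_types = c("Tumor", "CD8T", "TAM"))
  expect_s3_class(tidy(it), "tbl_df")
  g <- glance(it)
  expect_equal(g$n_pairs, 1L)
  expect_true(is.numeric(g$pi0))
})
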