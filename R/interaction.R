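# Labels aligned to the matrix rows; every cell must be annotated.
aligned_labels <- function(expr, annotation) {
  idx <- match(rownames(expr), annotation$barcode)
  if (anyNA(idx)) {
    abort_format(paste0(sum(is.na(idx)),
                        " matrix barcode(s) missing from the annotation"))
  }
  annotation$cell_type[idx]
}

# Mean expression of `genes` per cell type: a types x genes dense matrix.
type_mean_matrix <- function(expr, labels, types, genes) {
  e <- as.matrix(expr[, genes, drop = FALSE])
  m <- vapply(types, function(t) {
    sel <- labels == t
    if (!any(sel)) abort_config(paste0("no cells of type '", t, "'"))
    colMeans(e[sel, , drop = FALSE])
  }, numeric(length(genes)))
  matrix(t(m), nrow = length(types), ncol = length(genes),
         dimnames = list(types, genes))
}

#' Checkpoint interaction score
#'
#' The interaction level of a ligand-receptor axis between a sender
#' (ligand-contributing, e.g. an antigen-presenting cell) type and a
#' receiver (receptor-contributing, e.g. a T or NK cell) type is the product
#' of the mean ligand expression over sender cells and the mean receptor
#' expression over receiver cells, on log-normalized expression.
#'
#' @param expr Cell-by-gene normalized expression matrix.
#' @param annotation Tibble with `barcode` and `cell_type` covering all rows
#'   of `expr`.
#' @param ligand,receptor Gene symbols; a gene absent from the matrix gives
#'   score 0 with a warning.
#' @param sender_type,receiver_type Cell types; an empty group is an error
#'   naming the group.
#' @return The score, a single non-negative number.
#' @export
interaction_score <- function(expr, annotation, ligand, receptor,
                              sender_type, receiver_type) {
  labels <- aligned_labels(expr, annotation)
  for (t in c(sender_type, receiver_type)) {
    if (!any(labels == t)) abort_config(paste0("no cells of type '", t, "'"))
  }
  gene_mean <- function(gene, sel) {
    if (!gene %in% colnames(expr)) {
      warn(paste0("gene '", gene, "' absent from the matrix: treated as 0"))
      return(0)
    }
    mean(as.numeric(expr[sel, gene]))
  }
  gene_mean(ligand, labels == sender_type) *
    gene_mean(receptor, labels == receiver_type)
}

#' Permutation empirical P for one interaction axis
#'
#' Generates a null distribution for [interaction_score()] by shuffling cell
#' type labels while keeping every type's cell count fixed, and reports the
#' proportion of permuted scores exceeding the observed score. Under the
#' literal `"strict"` rule the p-value is `#(S_perm > S_obs) / B`, which is 0
#' on fully degenerate ties; the `"plus_one"` rule
#' `(#(S_perm >= S_obs) + 1) / (B + 1)` is never anti-conservative and is
#' the recommended alternative.
#'
#' @inheritParams interaction_score
#' @param B Number of permutations (>= 1).
#' @param seed Integer seed for the permutation draws.
#' @param mode `"strict"` (default) or `"plus_one"`; recorded in the output.
#' @param scope `"global"` shuffles the full label vector over all annotated
#'   cells; `"pair"` shuffles labels only among cells of the two involved
#'   types (faster, conditional null).
#' @param exhaustive If `TRUE` (pair scope only), enumerate every distinct
#'   assignment of group labels instead of sampling; `B` is ignored.
#' @return One-row tibble: `ligand`, `receptor`, `sender`, `receiver`,
#'   `score`, `p`, `n_perm`, `mode`, `scope`.
#' @export
permutation_p <- function(expr, annotation, ligand, receptor, sender_type,
                          receiver_type, B = 1000L, seed = NULL,
                          mode = c("strict", "plus_one"),
                          scope = c("global", "pair"), exhaustive = FALSE) {
  mode <- match.arg(mode)
  scope <- match.arg(scope)
  if (!exhaustive && B < 1) abort_config("B must be >= 1")
  # canonical barcode order: results do not depend on input cell order
  expr <- expr[order(rownames(expr)), , drop = FALSE]
  labels <- aligned_labels(expr, annotation)
  for (t in c(sender_type, receiver_type)) {
    if (!any(labels == t)) abort_config(paste0("no cells of type '", t, "'"))
  }
  lig_v <- if (ligand %in% colnames(expr)) {
    as.numeric(expr[, ligand])
  } else {
    warn(paste0("gene '", ligand, "' absent from the matrix: treated as 0"))
    numeric(nrow(expr))
  }
  rec_v <- if (receptor %in% colnames(expr)) {
    as.numeric(expr[, receptor])
  } else {
    warn(paste0("gene '", receptor, "' absent from the matrix: treated as 0"))
    numeric(nrow(expr))
  }
  s_obs <- mean(lig_v[labels == sender_type]) *
    mean(rec_v[labels == receiver_type])

  if (scope == "pair") {
    keep <- labels %in% c(sender_type, receiver_type)
    lig_v <- lig_v[keep]
    rec_v <- rec_v[keep]
    labels <- labels[keep]
  }
  n <- length(labels)

  if (exhaustive) {
    if (scope != "pair" || length(unique(labels)) != 2) {
      abort_config("exhaustive enumeration requires pair scope with 2 types")
    }
    n_s <- sum(labels == sender_type)
    combos <- utils::combn(n, n_s)
    s_perm <- apply(combos, 2L, function(idx) {
      mean(lig_v[idx]) * mean(rec_v[-idx])
    })
    n_perm <- length(s_perm)
  } else {
    s_perm <- with_seed(seed, {
      vapply(seq_len(B), function(b) {
        l <- labels[sample.int(n)]
        mean(lig_v[l == sender_type]) * mean(rec_v[l == receiver_type])
      }, numeric(1))
    })
    n_perm <- B
  }
  p <- if (mode == "strict") {
    sum(s_perm > s_obs) / n_perm
  } else {
    (sum(s_perm >= s_obs) + 1) / (n_perm + 1)
  }
  tibble(
    ligand = ligand, receptor = receptor, sender = sender_type,
    receiver = receiver_type, score = s_obs, p = p, n_perm = n_perm,
    mode = mode, scope = scope
  )
}

#' Permutation-tested checkpoint interaction panel
#'
#' Computes [interaction_score()] and its permutation empirical P for every
#' (axis, sender type, receiver type) triple of a checkpoint table, in one
#' pass: a single set of `B` global label permutations is drawn (seeded) and
#' shared across all triples, so all axes are tested against the same null
#' ensemble.
#'
#' @inheritParams permutation_p
#' @param pairs A ligand-receptor tibble with columns `axis`, `ligand`,
#'   `receptor` (see [read_lr_pairs()]).
#' @param sender_types,receiver_types Cell types contributing ligand and
#'   receptor respectively.
#' @return A `checkpoint_result` tibble: `axis`, `ligand`, `receptor`,
#'   `sender`, `receiver`, `score`, `p`, `n_perm`, `mode`. Axes whose genes
#'   are absent from the matrix get score 0 and `p = NA`.
#' @export
checkpoint_panel <- function(expr, annotation, pairs, sender_types,
                             receiver_types, B = 1000L, seed = NULL,
                             mode = c("strict", "plus_one")) {
  mode <- match.arg(mode)
  if (nrow(pairs) == 0) abort_config("empty ligand-receptor table")
  if (B < 1) abort_config("B must be >= 1")
  # canonical barcode order: results do not depend on input cell order
  expr <- expr[order(rownames(expr)), , drop = FALSE]
  labels <- aligned_labels(expr, annotation)
  types <- unique(c(sender_types, receiver_types))
  genes_all <- unique(c(pairs$ligand, pairs$receptor))
  present <- intersect(genes_all, colnames(expr))
  absent <- setdiff(genes_all, present)
  if (length(absent)) {
    warn(paste0(length(absent), " gene(s) absent from the matrix: ",
                paste(absent, collapse = ", ")))
  }
  has_genes <- pairs$ligand %in% present & pairs$receptor %in% present
  if (!any(has_genes)) abort_config("no axis is computable: all genes absent")

  combos <- tidyr::expand_grid(
    pairs[, c("axis", "ligand", "receptor")],
    sender = sender_types, receiver = receiver_types
  )
  computable <- combos$ligand %in% present & combos$receptor %in% present

  e <- as.matrix(expr[, present, drop = FALSE])
  grp <- lapply(setNames(types, types), function(t) which(labels == t))
  n_by_type <- lengths(grp)
  if (any(n_by_type == 0)) {
    abort_config(paste0("no cells of type '",
                        names(n_by_type)[n_by_type == 0][1], "'"))
  }
  m_ind <- sparseMatrix(
    i = rep(seq_along(types), n_by_type),
    j = unlist(grp, use.names = FALSE),
    x = rep(1 / n_by_type, n_by_type),
    dims = c(length(types), length(labels))
  )
  obs_means <- as.matrix(m_ind %*% e)
  dimnames(obs_means) <- list(types, present)

  li <- match(combos$ligand[computable], present)
  ri <- match(combos$receptor[computable], present)
  si <- match(combos$sender[computable], types)
  rci <- match(combos$receiver[computable], types)
  s_obs <- obs_means[cbind(si, li)] * obs_means[cbind(rci, ri)]

  n <- length(labels)
  cnt_gt <- numeric(length(s_obs))
  cnt_ge <- numeric(length(s_obs))
  with_seed(seed, {
    for (b in seq_len(B)) {
      perm <- sample.int(n)
      pm <- as.matrix(m_ind %*% e[perm, , drop = FALSE])
      s_perm <- pm[cbind(si, li)] * pm[cbind(rci, ri)]
      cnt_gt <- cnt_gt + (s_perm > s_obs)
      cnt_ge <- cnt_ge + (s_perm >= s_obs)
    }
  })
  p <- if (mode == "strict") cnt_gt / B else (cnt_ge + 1) / (B + 1)

  combos$score <- 0
  combos$p <- NA_real_
  combos$score[computable] <- s_obs
  combos$p[computable] <- p
  combos$n_perm <- B
  combos$mode <- mode
  class(combos) <- c("checkpoint_result", class(combos))
  combos
}

# One-sample one-sided (greater) Wilcoxon signed-rank p-value. Zeros are
# dropped per the standard signed-rank convention; exact null for n <= 25
# without ties, normal approximation with continuity correction otherwise.
# An empty (all-zero) sample carries no evidence: p = 1.
wilcoxon_signed_p <- function(x, exact_max = 25L) {
  x <- x[x != 0]
  n <- length(x)
  if (n == 0) return(1)
  exact <- n <= exact_max && !any(duplicated(abs(x)))
  suppressWarnings(
    wilcox.test(x, mu = 0, alternative = "greater", exact = exact,
                correct = TRUE)$p.value
  )
}

#' Storey q-values
#'
#' False-discovery-rate q-values with the null proportion pi0 estimated by
#' the smoother method: pi0(lambda) = #(p > lambda) / (m (1 - lambda)) is
#' fit with a natural cubic spline (3 df) over the lambda grid and evaluated
#' at the largest lambda, then clamped to (0, 1]. Setting `pi0 = 1` recovers
#' Benjamini-Hochberg adjusted p-values.
#'
#' @param p Vector of p-values in \[0, 1\].
#' @param lambda Grid for the pi0 smoother (default 0.05 to 0.95 by 0.05).
#' @param pi0 Optional fixed null proportion overriding the estimate.
#' @return Numeric q-values, monotone in `p`, with the pi0 used attached as
#'   attribute `"pi0"`.
#' @export
storey_qvalue <- function(p, lambda = seq(0.05, 0.95, by = 0.05), pi0 = NULL) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    abort_config("p-values must lie in [0, 1]")
  }
  m <- length(p)
  if (m == 0) return(numeric(0))
  if (is.null(pi0)) {
    lambda <- sort(lambda)
    pi0_l <- vapply(lambda, function(l) mean(p > l) / (1 - l), numeric(1))
    pi0 <- if (length(lambda) >= 4) {
      fit <- smooth.spline(lambda, pi0_l, df = 3)
      predict(fit, x = max(lambda))$y
    } else {
      pi0_l[[length(pi0_l)]]
    }
  }
  pi0 <- min(pi0, 1)
  pi0 <- max(pi0, .Machine$double.eps)
  r <- rank(p, ties.method = "max")
  q <- pi0 * m * p / r
  o <- order(p, decreasing = TRUE)
  q[o] <- cummin(q[o])
  q <- pmin(q, 1)
  attr(q, "pi0") <- pi0
  q
}

#' Pan-ligand-receptor interactome scoring
#'
#' For every curated ligand-receptor pair, computes the interaction score
#' over all ordered (sender, receiver) cell-type pairs with sender !=
#' receiver, tests with a one-sided one-sample Wilcoxon signed-rank test
#' whether the median score across cell-type pairs exceeds zero, corrects
#' across pairs with Storey q-values, and calls a pair significant when its
#' median score exceeds `score_threshold` and its q-value is below
#' `q_threshold` (defaults 0.5 and 0.05).
#'
#' @inheritParams checkpoint_panel
#' @param cell_types Types to cross (default: all annotated types); >= 2
#'   required.
#' @param score_threshold,q_threshold Significance thresholds on the median
#'   per-pair score and the Storey q-value.
#' @param lambda Passed to [storey_qvalue()].
#' @param pi0 Optional fixed pi0 passed to [storey_qvalue()].
#' @return An `interactome_result`: list with `scores` (long tibble: axis,
#'   ligand, receptor, sender, receiver, score), `summary` (tibble: axis,
#'   ligand, receptor, n_type_pairs, median_score, wilcoxon_p, storey_q,
#'   significant) and `params`.
#' @export
interactome <- function(expr, annotation, pairs, cell_types = NULL,
                        score_threshold = 0.5, q_threshold = 0.05,
                        lambda = seq(0.05, 0.95, by = 0.05), pi0 = NULL) {
  if (nrow(pairs) == 0) abort_config("empty ligand-receptor table")
  labels <- aligned_labels(expr, annotation)
  cell_types <- cell_types %||% sort(unique(labels))
  if (length(cell_types) < 2) abort_config("need >= 2 cell types")
  genes_all <- unique(c(pairs$ligand, pairs$receptor))
  present <- intersect(genes_all, colnames(expr))
  absent <- setdiff(genes_all, present)
  if (length(absent)) {
    warn(paste0(length(absent),
                " gene(s) absent from the matrix scored as 0"))
  }
  means <- type_mean_matrix(expr, labels, cell_types, present)
  tp <- tidyr::expand_grid(sender = cell_types, receiver = cell_types) |>
    filter(.data$sender != .data$receiver)

  scores <- tidyr::expand_grid(
    pairs[, c("axis", "ligand", "receptor")], tp
  )
  scores$score <- mapply(function(l, r, s, rc) {
    (if (l %in% present) means[s, l] else 0) *
      (if (r %in% present) means[rc, r] else 0)
  }, scores$ligand, scores$receptor, scores$sender, scores$receiver,
  USE.NAMES = FALSE)

  summary <- scores |>
    group_by(.data$axis, .data$ligand, .data$receptor) |>
    summarise(
      n_type_pairs = dplyr::n(),
      median_score = median(.data$score),
      wilcoxon_p = wilcoxon_signed_p(.data$score),
      .groups = "drop"
    )
  # preserve the pair-table order deterministically
  key <- function(d) paste(d$axis, d$ligand, d$receptor, sep = "\r")
  summary <- summary[match(key(pairs), key(summary)), ]
  q <- storey_qvalue(summary$wilcoxon_p, lambda = lambda, pi0 = pi0)
  summary$storey_q <- as.numeric(q)
  summary$significant <- summary$median_score > score_threshold &
    summary$storey_q < q_threshold

  structure(
    list(
      scores = scores, summary = summary,
      params = list(cell_types = cell_types,
                    score_threshold = score_threshold,
                    q_threshold = q_threshold, pi0 = attr(q, "pi0"))
    ),
    class = "interactome_result"
  )
}

#' @export
print.interactome_result <- function(x, ...) {
  cat("interactome_result:", nrow(x$summary), "pairs x",
      nrow(x$scores) / max(1, nrow(x$summary)), "cell-type pairs;",
      sum(x$summary$significant), "significant (score >",
      x$params$score_threshold, "& q <", x$params$q_threshold, ")\n")
  invisible(x)
}
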