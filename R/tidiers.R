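#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @describeIn interactome Tidy per-pair summary of an interactome result.
#' @param x An `interactome_result`.
#' @param ... Unused.
#' @method tidy interactome_result
#' @export
tidy.interactome_result <- function(x, ...) x$summary

#' @describeIn interactome One-row overview of an interactome result.
#' @method glance interactome_result
#' @export
glance.interactome_result <- function(x, ...) {
  tibble(
    n_pairs = nrow(x$summary),
    n_significant = sum(x$summary$significant),
    pi0 = x$params$pi0,
    score_threshold = x$params$score_threshold,
    q_threshold = x$params$q_threshold
  )
}

#' @describeIn cluster_cnv_groups Per-cell group labels as a tibble.
#' @param x A `cnv_grouping`.
#' @param ... Unused.
#' @method tidy cnv_grouping
#' @export
tidy.cnv_grouping <- function(x, ...) x$groups

#' @describeIn cluster_cnv_groups One-row overview of a CNV grouping.
#' @method glance cnv_grouping
#' @export
glance.cnv_grouping <- function(x, ...) {
  tibble(k = x$k, n_cells = nrow(x$groups))
}

#' @describeIn lcsc_groups Per-cell group labels as a tibble.
#' @param x An `lcsc_grouping`.
#' @param ... Unused.
#' @method tidy lcsc_grouping
#' @export
tidy.lcsc_grouping <- function(x, ...) x$groups

#' @describeIn lcsc_groups One-row overview of an LCSC grouping.
#' @method glance lcsc_grouping
#' @export
glance.lcsc_grouping <- function(x, ...) {
  tibble(k = length(unique(x$groups$group)),
         n_cells = nrow(x$groups),
         n_panel_genes = length(x$panel_used))
}
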