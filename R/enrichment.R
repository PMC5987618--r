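#' Select the top fraction of genes by score
#'
#' Returns the `k = floor(fraction * n)` genes with the highest scores.
#' Ties at the boundary are broken by the lexicographically smaller gene
#' id, so the selection is deterministic. (Note: with n = 2041 and
#' fraction 0.05 this rule gives k = 102.)
#'
#' @param scores Tibble `gene_id`, `score` (one row per gene).
#' @param fraction Fraction of genes to keep, in (0, 1); default 0.05.
#' @return Character vector of selected gene ids.
#' @export
top_fraction <- function(scores, fraction = 0.05) {
  stopifnot(fraction > 0, fraction < 1)
  if (nrow(scores) == 0L) stop("empty score table")
  k <- floor(fraction * nrow(scores))
  scores |>
    dplyr::arrange(dplyr::desc(.data$score), .data$gene_id) |>
    dplyr::slice_head(n = k) |>
    dplyr::pull("gene_id")
}

#' Term over-representation by Fisher's exact test
#'
#' One-sided (enrichment-only) test per term: the p-value is the
#' hypergeometric upper-tail probability of seeing at least `k` annotated
#' genes when drawing `n` genes (the test set) from a universe of `N`
#' baseline genes of which `K` carry the term. This equals the one-sided
#' Fisher exact p of the corresponding 2x2 table. P-values are adjusted
#' across terms by Benjamini-Hochberg (see [adjust_pvalues()]).
#'
#' @param test_genes Character vector of test-set gene ids; must be a
#'   subset of the baseline.
#' @param baseline_genes Character vector: the gene universe.
#' @param annotations Tibble `gene_id`, `term_id`, and optionally
#'   `term_name`, `category`.
#' @return A tibble, one row per term with at least one annotated baseline
#'   gene: `term_id` (plus `term_name`/`category` if supplied), `k`, `K`,
#'   `n`, `N`, `p_value`, `p_adjust`, sorted by adjusted then raw p.
#' @export
fisher_enrichment <- function(test_genes, baseline_genes, annotations) {
  if (length(test_genes) == 0L) stop("empty test set")
  if (!all(test_genes %in% baseline_genes))
    stop("test set is not a subset of the baseline universe")
  ann <- dplyr::filter(annotations, .data$gene_id %in% baseline_genes) |>
    dplyr::distinct(.data$gene_id, .data$term_id, .keep_all = TRUE)
  n <- length(unique(test_genes))
  N <- length(unique(baseline_genes))
  meta_cols <- intersect(c("term_name", "category"), names(ann))
  out <- ann |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c("term_id", meta_cols)))) |>
    dplyr::summarise(
      K = dplyr::n_distinct(.data$gene_id),
      k = sum(unique(.data$gene_id) %in% test_genes),
      .groups = "drop") |>
    dplyr::mutate(
      n = n, N = N,
      p_value = stats::phyper(.data$k - 1L, .data$K, N - .data$K, n,
                              lower.tail = FALSE),
      p_adjust = adjust_pvalues(.data$p_value)) |>
    dplyr::arrange(.data$p_adjust, .data$p_value, .data$term_id)
  out
}

#' Adjust p-values for multiple testing
#'
#' Benjamini-Hochberg step-up adjustment by default (any method accepted
#' by [stats::p.adjust()] may be named). Output preserves input order and
#' is monotone in the usual step-up sense.
#'
#' @param p Numeric vector of raw p-values in (0, 1].
#' @param method Adjustment method (default `"BH"`).
#' @return Adjusted p-values, same length and order as `p`.
#' @export
adjust_pvalues <- function(p, method = "BH") {
  stats::p.adjust(p, method = method)
}
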