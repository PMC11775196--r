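#' Gene-set over-representation analysis
#'
#' One-sided hypergeometric (Fisher upper-tail) test of a query gene list
#' against each term of a gene-set collection, with Benjamini-Hochberg
#' adjustment across all tested terms. For a universe of `N` genes, a term of
#' size `K`, a query of size `n` and an observed intersection `k`, the
#' p-value is `P[X >= k]` for `X ~ Hypergeometric(N, K, n)`, computed exactly.
#'
#' @param query Character vector of query genes (upper-cased internally).
#' @param gene_sets A long gene-set tibble (`term`, `gene`; optionally
#'   `description`), e.g. from [read_gene_sets()].
#' @param universe Optional background gene vector; defaults to all genes in
#'   `gene_sets`. Query genes outside the universe are dropped with a
#'   warning; terms are intersected with the universe.
#' @param padj_threshold Threshold on the adjusted p (strict `<`); 0.001 and
#'   0.05 are common reporting cuts.
#' @return A tibble of class `ps_enrichment`: `term`, `k`, `K`, `n`, `N`,
#'   `p`, `p_adj`, `enriched`, sorted by `p`.
#' @export
enrich <- function(query, gene_sets, universe = NULL,
                   padj_threshold = 0.05) {
  gene_sets <- as_tibble(gene_sets) %>%
    mutate(term = .data$term, gene = toupper(.data$gene))
  if (is.null(universe)) {
    universe <- unique(gene_sets$gene)
  } else {
    universe <- unique(toupper(universe))
  }
  if (length(universe) == 0) abort("empty universe")
  query <- unique(toupper(query))
  outside <- setdiff(query, universe)
  if (length(outside) > 0) {
    warn(paste0(length(outside), " query gene(s) outside the universe dropped"))
    query <- intersect(query, universe)
  }
  N <- length(universe)
  n <- length(query)
  out <- gene_sets %>%
    filter(.data$gene %in% universe) %>%
    group_by(.data$term) %>%
    summarise(
      K = dplyr::n_distinct(.data$gene),
      k = dplyr::n_distinct(intersect(.data$gene, query)),
      .groups = "drop"
    ) %>%
    mutate(
      n = n, N = N,
      p = phyper(.data$k - 1, .data$K, N - .data$K, n, lower.tail = FALSE),
      p_adj = p.adjust(.data$p, method = "BH"),
      enriched = .data$p_adj < padj_threshold
    ) %>%
    select("term", "k", "K", "n", "N", "p", "p_adj", "enriched") %>%
    arrange(.data$p, .data$term)
  attr(out, "padj_threshold") <- padj_threshold
  class(out) <- c("ps_enrichment", class(out))
  out
}

#' Terms enriched in both an interactome and a targetome
#'
#' Intersects the enriched term sets of two enrichment results (e.g. one on
#' an HCI list, one on a ChIP-seq targetome), carrying both adjusted
#' p-values.
#'
#' @param enrich_interactome,enrich_targetome `ps_enrichment` tibbles.
#' @return A tibble `term`, `p_adj_interactome`, `p_adj_targetome`.
#' @export
common_terms <- function(enrich_interactome, enrich_targetome) {
  a <- as_tibble(enrich_interactome) %>%
    filter(.data$enriched) %>%
    select("term", p_adj_interactome = "p_adj")
  b <- as_tibble(enrich_targetome) %>%
    filter(.data$enriched) %>%
    select("term", p_adj_targetome = "p_adj")
  inner_join(a, b, by = "term") %>% arrange(.data$term)
}
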