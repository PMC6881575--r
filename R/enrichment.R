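## Term (GO/KEGG-style) over-representation of DE gene sets: exact
## hypergeometric upper tail, Fisher's exact test, the conservative EASE
## variant, BH across terms, the "10 smallest p-values" display rule,
## and the pathway-gene bipartite network.

#' Exact hypergeometric upper-tail p-value
#'
#' `P(X >= k)` where `X ~ Hypergeometric(N, K, n)`: the probability of
#' drawing at least `k` annotated genes when `n` genes are drawn from a
#' universe of `N` containing `K` annotated ones. Computed by exact
#' summation of [stats::dhyper()] masses.
#'
#' @param k observed overlap (DE genes in the term).
#' @param K term size in the universe.
#' @param n number of DE genes drawn.
#' @param N universe size.
#' @return p-value in \[0, 1\].
#' @examples
#' hypergeom_pvalue(5, 5, 5, 10)  # 1 / choose(10, 5)
#' @export
hypergeom_pvalue <- function(k, K, n, N) {
  check_number(k, "k", lower = 0, integer = TRUE)
  check_number(K, "K", lower = 0, integer = TRUE)
  check_number(n, "n", lower = 0, integer = TRUE)
  check_number(N, "N", lower = 1, integer = TRUE)
  if (K > N || n > N || k > min(K, n))
    stop_domain("inconsistent counts: need k <= min(K, n), K <= N, n <= N")
  if (k == 0) return(1)
  sum(stats::dhyper(k:min(K, n), K, N - K, n))
}

#' EASE-score p-value (one-gene-discounted hypergeometric tail)
#'
#' The conservative variant used by DAVID/EASE: one gene is removed from
#' the overlap before computing the hypergeometric upper tail, i.e.
#' `hypergeom_pvalue(max(k - 1, 0), K, n, N)`. Always at least as large
#' as the plain hypergeometric p.
#'
#' @inheritParams hypergeom_pvalue
#' @return p-value in \[0, 1\].
#' @export
ease_pvalue <- function(k, K, n, N) {
  check_number(k, "k", lower = 0, integer = TRUE)
  hypergeom_pvalue(max(k - 1, 0), K, n, N)
}

#' @noRd
fisher_pvalue <- function(k, K, n, N) {
  tab <- matrix(c(k, n - k, K - k, N - K - n + k), nrow = 2)
  stats::fisher.test(tab, alternative = "greater")$p.value
}

#' Term over-representation analysis of a DE gene set
#'
#' Tests every term with at least one universe gene, adjusts with BH
#' across all tested terms, keeps terms with raw `p < p_max` (the
#' display rule filters on raw p; q is reported alongside), sorts by
#' ascending p with ties broken by term id, and truncates to the `top`
#' smallest (all significant terms are returned when fewer than `top`
#' pass).
#'
#' @param de_genes DE gene ids (genes outside the universe are dropped
#'   with a warning).
#' @param term_table data frame with columns `term_id`, `gene_id`
#'   (optionally `term_name`).
#' @param universe character vector of all measurable gene ids.
#' @param method `"hypergeom"` (default), `"fisher"` or `"ease"`.
#' @param p_max raw p-value cutoff (default 0.05).
#' @param top number of items displayed (default 10).
#' @return object of class `enrichment_result`: data frame with columns
#'   `term_id`, `term_name`, `k`, `K`, `n`, `N`, `p`, `q`,
#'   `fold_enrichment`; attribute `n_terms_tested`.
#' @export
enrich_terms <- function(de_genes, term_table, universe,
                         method = c("hypergeom", "fisher", "ease"),
                         p_max = 0.05, top = 10) {
  method <- match.arg(method)
  universe <- unique(as.character(universe))
  N <- length(universe)
  if (N == 0L) stop_domain("empty universe")
  de_genes <- unique(as.character(de_genes))
  outside <- setdiff(de_genes, universe)
  if (length(outside) > 0L) {
    warning(length(outside), " DE gene(s) outside the universe dropped")
    de_genes <- intersect(de_genes, universe)
  }
  n <- length(de_genes)
  if (!all(c("term_id", "gene_id") %in% names(term_table)))
    stop_domain("'term_table' needs columns term_id, gene_id")
  term_table <- term_table[term_table$gene_id %in% universe, ,
                           drop = FALSE]
  terms <- split(unique(term_table[, c("term_id", "gene_id")])$gene_id,
                 unique(term_table[, c("term_id", "gene_id")])$term_id)
  names_map <- NULL
  if ("term_name" %in% names(term_table))
    names_map <- tapply(term_table$term_name, term_table$term_id,
                        function(x) x[[1L]])
  pfun <- switch(method, hypergeom = hypergeom_pvalue,
                 fisher = fisher_pvalue, ease = ease_pvalue)
  rows <- lapply(names(terms), function(tid) {
    genes <- terms[[tid]]
    K <- length(genes)
    k <- length(intersect(genes, de_genes))
    data.frame(term_id = tid,
               term_name = if (!is.null(names_map))
                 unname(names_map[tid]) else tid,
               k = k, K = K, n = n, N = N,
               p = pfun(k, K, n, N),
               fold_enrichment = if (n > 0 && K > 0)
                 (k / n) / (K / N) else 0,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  n_tested <- nrow(res)
  res$q <- bh_adjust(res$p)
  res <- res[res$p < p_max, , drop = FALSE]
  res <- res[order(res$p, res$term_id), , drop = FALSE]
  res <- utils::head(res, top)
  res <- res[, c("term_id", "term_name", "k", "K", "n", "N", "p", "q",
                 "fold_enrichment")]
  rownames(res) <- NULL
  structure(res, n_terms_tested = n_tested,
            class = c("enrichment_result", "data.frame"))
}

#' Pathway-gene bipartite network from enrichment results
#'
#' One edge per (significant term, DE gene annotated to that term).
#'
#' @param results an [enrich_terms()] result.
#' @param de_genes the DE gene set used for the enrichment.
#' @param term_table the term-to-gene table used for the enrichment.
#' @return data frame `term_id`, `gene_id`, sorted.
#' @export
pathway_gene_network <- function(results, de_genes, term_table) {
  tt <- unique(term_table[term_table$term_id %in% results$term_id &
                            term_table$gene_id %in% de_genes,
                          c("term_id", "gene_id")])
  tt <- tt[order(tt$term_id, tt$gene_id), , drop = FALSE]
  rownames(tt) <- NULL
  tt
}
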