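## Synthetic PFMs, lncRNA promoter sequences with planted motif sites,
## TF target gene sets, and a term-to-gene table with one planted
## over-represented term.

#' Simulate PFMs, promoters, TF targets and the term table
#'
#' Builds `n_tf` informative PFMs (one dominant base per column, widths
#' 12-15), a promoter sequence for every lncRNA (length `promoter_up +
#' promoter_down`), and plants each PFM's consensus into a subset of
#' the DE lncRNA promoters at recorded offsets and strands. Also
#' assigns each TF a target gene set enriched for DE mRNAs (so the
#' trans-regulation chain is recoverable) and emits a term table in
#' which the first term's gene set is over-represented among the DE
#' mRNAs.
#'
#' @param config a [sim_config()].
#' @param de_truth optional truth from [simulate_expression()]; when
#'   given, motifs are planted into DE lncRNA promoters and the
#'   enriched term / TF target sets draw from DE mRNAs; otherwise the
#'   first transcripts of each class stand in.
#' @return list with `pfms` (list of [pfm()]), `promoters` (named
#'   character vector, DNA), `tf_targets` (named list of gene ids),
#'   `term_table` (data frame `term_id`, `term_name`, `gene_id`), and
#'   `truth` (`motif_sites`, `tf_targets`, `enriched_term`).
#' @export
simulate_motifs_and_terms <- function(config, de_truth = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derive_seeds(config$seed, 4)[4L])
  ids <- probe_ids_for(config)
  prom_len <- config$promoter_up + config$promoter_down
  truth <- empty_truth()

  ## informative PFMs: dominant base count 85, others 5 per column
  pfms <- lapply(seq_len(config$n_tf), function(i) {
    width <- sample(12:15, 1)
    if (prom_len < width)
      stop_domain("PFM width exceeds promoter length")
    dom <- sample(1:4, width, replace = TRUE)
    counts <- matrix(5, 4, width)
    counts[cbind(dom, seq_len(width))] <- 85
    pfm(sprintf("TF%02d", i), counts)
  })
  names(pfms) <- vapply(pfms, `[[`, "", "tf_name")

  promoters <- stats::setNames(
    vapply(ids$lncrna, function(i) random_dna(prom_len, config$base_freq),
           ""), ids$lncrna)

  de_all <- if (!is.null(de_truth))
    c(de_truth$de_ids_up, de_truth$de_ids_down) else character(0)
  host_lncs <- intersect(ids$lncrna, de_all)
  if (length(host_lncs) == 0L)
    host_lncs <- utils::head(ids$lncrna, max(4L, config$n_tf))
  de_mrna <- intersect(ids$mrna, de_all)
  if (length(de_mrna) == 0L) de_mrna <- utils::head(ids$mrna, 20L)

  ## plant each TF's consensus into ~60% of host promoters (>= 1 each)
  sites <- list()
  for (p in pfms) {
    cons <- pfm_consensus(p)
    w <- nchar(cons)
    n_hosts <- max(1L, round(0.6 * length(host_lncs)))
    hosts <- sample(host_lncs, n_hosts)
    for (h in hosts) {
      offset <- sample(0:(prom_len - w), 1)
      strand <- sample(c("+", "-"), 1)
      insert <- if (strand == "+") cons else revcomp_dna(cons)
      substr(promoters[[h]], offset + 1L, offset + w) <- insert
      sites[[length(sites) + 1L]] <- data.frame(
        tf = p$tf_name, lncrna_id = h, offset = offset, strand = strand,
        stringsAsFactors = FALSE)
    }
  }
  if (length(sites) > 0L) {
    truth$motif_sites <- do.call(rbind, sites)
    ## overlapping plants in one promoter can clobber each other; keep
    ## only sites whose consensus survived intact on the recorded strand
    survives <- vapply(seq_len(nrow(truth$motif_sites)), function(i) {
      s <- truth$motif_sites[i, ]
      cons <- pfm_consensus(pfms[[s$tf]])
      w <- nchar(cons)
      word <- substr(promoters[[s$lncrna_id]], s$offset + 1L, s$offset + w)
      word == (if (s$strand == "+") cons else revcomp_dna(cons))
    }, TRUE)
    truth$motif_sites <- truth$motif_sites[survives, , drop = FALSE]
    rownames(truth$motif_sites) <- NULL
  }

  ## TF target gene sets: 40 genes, ~25 of them DE mRNAs
  tf_targets <- lapply(pfms, function(p) {
    n_de <- min(25L, length(de_mrna))
    n_bg <- max(0L, 40L - n_de)
    sort(unique(c(sample(de_mrna, n_de),
                  sample(setdiff(ids$mrna, de_mrna),
                         min(n_bg, config$n_mrna - length(de_mrna))))))
  })
  names(tf_targets) <- names(pfms)
  truth$tf_targets <- tf_targets

  ## term table: the first term is over-represented in the DE mRNA set
  if (config$n_terms > 0L) {
    term_ids <- sprintf("TERM%03d", seq_len(config$n_terms))
    rows <- list()
    n_de_in <- min(config$enriched_term_de, length(de_mrna),
                   config$term_size)
    planted_genes <- c(sample(de_mrna, n_de_in),
                       sample(setdiff(ids$mrna, de_mrna),
                              config$term_size - n_de_in))
    rows[[1L]] <- data.frame(term_id = term_ids[1L],
                             term_name = "planted_pathway",
                             gene_id = sort(planted_genes),
                             stringsAsFactors = FALSE)
    for (t in seq_len(config$n_terms)[-1L])
      rows[[t]] <- data.frame(
        term_id = term_ids[t],
        term_name = sprintf("background_pathway_%03d", t),
        gene_id = sort(sample(ids$mrna, config$term_size)),
        stringsAsFactors = FALSE)
    term_table <- do.call(rbind, rows)
    truth$enriched_term <- term_ids[1L]
  } else {
    term_table <- data.frame(term_id = character(0),
                             term_name = character(0),
                             gene_id = character(0),
                             stringsAsFactors = FALSE)
  }

  list(pfms = pfms, promoters = promoters, tf_targets = tf_targets,
       term_table = term_table, truth = truth)
}
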