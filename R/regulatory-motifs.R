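## Trans-regulation: position-frequency-matrix scanning of lncRNA
## promoters, exact E-value tails via dynamic programming over the
## per-column score distributions, the TF-lncRNA bipartite network,
## hypergeometric TF-target enrichment, and the lncRNA-TF-mRNA ternary
## network.

## Granularity (bits) used to put log-odds scores on a fixed lattice so
## the tail-distribution DP is exact for the published matrix.
PWM_GRANULARITY <- 1e-3

#' Construct a position frequency matrix
#'
#' @param tf_name transcription factor name.
#' @param counts numeric matrix, 4 rows (A, C, G, T) x width >= 4, of
#'   non-negative observation counts; every column must have a positive
#'   sum.
#' @param pseudocount small positive value added per cell when converting
#'   to probabilities (default 0.25).
#' @return object of class `pfm`.
#' @export
pfm <- function(tf_name, counts, pseudocount = 0.25) {
  counts <- as.matrix(counts)
  if (nrow(counts) != 4L) stop_domain("'counts' must have 4 rows (A,C,G,T)")
  if (ncol(counts) < 4L) stop_domain("PFM width must be >= 4")
  if (any(counts < 0)) stop_domain("counts must be non-negative")
  if (any(colSums(counts) <= 0)) stop_domain("every column needs a positive sum")
  check_number(pseudocount, "pseudocount", lower = 1e-12)
  rownames(counts) <- DNA_BASES
  structure(list(tf_name = tf_name, counts = counts,
                 pseudocount = pseudocount),
            class = "pfm")
}

#' @export
print.pfm <- function(x, ...) {
  cat(sprintf("PFM %s: width %d, consensus %s\n", x$tf_name,
              ncol(x$counts), pfm_consensus(x)))
  invisible(x)
}

#' Consensus string of a PFM (columnwise argmax base)
#' @param x a [pfm()] object.
#' @return character string over A, C, G, T.
#' @export
pfm_consensus <- function(x) {
  paste(DNA_BASES[apply(x$counts, 2, which.max)], collapse = "")
}

#' Log-odds position weight matrix in bits
#'
#' Converts PFM counts to a log2 weight matrix against a background:
#' `w[b, i] = log2( (counts[b, i] + pc) / (colsum_i + 4 pc) / bg[b] )`.
#' Scores are rounded to a fixed lattice (`granularity` bits, default
#' 1e-3) so that the exact dynamic-programming tail distribution in
#' [pwm_score_distribution()] applies to the matrix exactly as
#' published.
#'
#' @param x a [pfm()] object.
#' @param background base frequencies (A, C, G, T), positive, summing
#'   to 1. Default uniform.
#' @param granularity score lattice in bits; `0` disables rounding.
#' @return 4 x width numeric matrix of weights in bits.
#' @export
pfm_log_odds <- function(x, background = rep(0.25, 4),
                         granularity = PWM_GRANULARITY) {
  stopifnot(inherits(x, "pfm"))
  if (length(background) != 4L || any(background <= 0) ||
      abs(sum(background) - 1) > 1e-8)
    stop_domain("'background' must be 4 positive frequencies summing to 1")
  cs <- colSums(x$counts)
  prob <- sweep(x$counts + x$pseudocount, 2, cs + 4 * x$pseudocount, "/")
  w <- log2(prob / background)
  if (granularity > 0) w <- round(w / granularity) * granularity
  rownames(w) <- DNA_BASES
  w
}

#' @noRd
encode_dna <- function(seq) {
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1L]]
  idx <- match(chars, DNA_BASES)
  idx  # NA marks ambiguous bases
}

#' Scan a promoter sequence with a position weight matrix
#'
#' Scores every offset of the promoter on the forward strand and, if
#' requested, on the reverse complement. Ambiguous bases contribute
#' their background-expected weight (and are counted in the
#' `n_ambiguous` attribute).
#'
#' @param pwm weight matrix from [pfm_log_odds()].
#' @param promoter_sequence DNA string, length >= PWM width.
#' @param both_strands scan the reverse complement too (default `TRUE`).
#' @param background base frequencies used for ambiguous-base scoring.
#' @return data frame with `offset` (0-based, on the forward sequence),
#'   `strand`, `score` (bits), ordered by offset then strand.
#' @export
scan_promoter <- function(pwm, promoter_sequence, both_strands = TRUE,
                          background = rep(0.25, 4)) {
  w <- ncol(pwm)
  L <- nchar(promoter_sequence)
  if (L < w) stop_domain("promoter shorter than PWM width")
  expected <- as.numeric(background %*% pwm)  # per-column bg-expected weight
  score_strand <- function(seq) {
    idx <- encode_dna(seq)
    n_amb <- sum(is.na(idx))
    nw <- L - w + 1L
    sc <- numeric(nw)
    for (j in seq_len(w)) {
      col <- pwm[, j]
      contrib <- col[idx[j:(j + nw - 1L)]]
      contrib[is.na(contrib)] <- expected[j]
      sc <- sc + contrib
    }
    list(sc = sc, n_amb = n_amb)
  }
  fwd <- score_strand(promoter_sequence)
  out <- data.frame(offset = 0:(L - w), strand = "+", score = fwd$sc,
                    stringsAsFactors = FALSE)
  n_amb <- fwd$n_amb
  if (both_strands) {
    rev <- score_strand(revcomp_dna(toupper(promoter_sequence)))
    ## offset reported on the forward coordinate of the site start
    rout <- data.frame(offset = (L - w):0, strand = "-", score = rev$sc,
                       stringsAsFactors = FALSE)
    out <- rbind(out, rout)
    n_amb <- n_amb  # same bases, counted once
  }
  out <- out[order(out$offset, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_ambiguous") <- n_amb
  out
}

#' Exact background score distribution of a PWM
#'
#' Dynamic programming over the per-column score values: the score of a
#' random background word is the sum of one weight per column, so its
#' distribution is the convolution of the column distributions. Weights
#' are placed on an integer lattice (the granularity used by
#' [pfm_log_odds()]), which makes the DP exact; the result matches
#' exhaustive enumeration of all `4^width` words.
#'
#' @param pwm weight matrix from [pfm_log_odds()].
#' @param background base frequencies (A, C, G, T).
#' @param granularity lattice size in bits (must match the matrix; the
#'   default is the [pfm_log_odds()] default).
#' @return list with `score` (ascending lattice values, bits), `prob`
#'   (point masses), and `tail` where `tail[i] = P(S >= score[i])`.
#' @export
pwm_score_distribution <- function(pwm, background = rep(0.25, 4),
                                   granularity = PWM_GRANULARITY) {
  iw <- round(pwm / granularity)
  width <- ncol(iw)
  cur <- 1
  cur_lo <- 0
  for (j in seq_len(width)) {
    col <- iw[, j]
    cmin <- min(col)
    width_units <- max(col) - cmin
    new_len <- length(cur) + width_units
    new <- numeric(new_len)
    for (b in 1:4) {
      off <- col[b] - cmin
      new[(1L + off):(length(cur) + off)] <-
        new[(1L + off):(length(cur) + off)] + background[b] * cur
    }
    cur <- new
    cur_lo <- cur_lo + cmin
  }
  score_units <- cur_lo + seq_along(cur) - 1L
  keep <- cur > 0
  prob <- cur[keep]
  score_units <- score_units[keep]
  tail <- rev(cumsum(rev(prob)))
  list(score = score_units * granularity, prob = prob, tail = tail)
}

## P(S >= threshold), vectorized over thresholds; thresholds are snapped
## to the score lattice to avoid floating-point boundary effects.
#' @noRd
tail_prob_at <- function(dist, threshold, granularity = PWM_GRANULARITY) {
  t_units <- round(threshold / granularity)
  s_units <- round(dist$score / granularity)
  pos <- findInterval(t_units - 0.5, s_units) + 1L
  out <- numeric(length(threshold))
  inside <- pos <= length(s_units)
  out[inside] <- dist$tail[pos[inside]]
  out
}

#' E-value of a motif score threshold over a scan
#'
#' Expected number of background positions scoring at or above the
#' threshold: `E = P(background position >= threshold) * n positions
#' scanned`, with the per-position tail probability computed exactly by
#' dynamic programming over the column score distributions.
#'
#' @param score_threshold score in bits.
#' @param pwm weight matrix from [pfm_log_odds()].
#' @param background base frequencies.
#' @param n_positions_scanned total positions scanned (all promoters,
#'   both strands), >= 1.
#' @return expected background hit count (>= 0).
#' @export
site_evalue <- function(score_threshold, pwm, background = rep(0.25, 4),
                        n_positions_scanned = 1) {
  check_number(n_positions_scanned, "n_positions_scanned", lower = 1)
  dist <- pwm_score_distribution(pwm, background)
  tail_prob_at(dist, score_threshold) * n_positions_scanned
}

#' Build the TF-lncRNA bipartite network by promoter scanning
#'
#' Scans every promoter with every PFM (both strands), converts each
#' hit's score to an E-value over the whole scan of that PFM (all
#' promoters, both strands), and draws an edge (TF, lncRNA) when at
#' least one hit has `e_value < e_max`.
#'
#' @param pfms list of [pfm()] objects.
#' @param promoters named character vector (or list) of promoter DNA
#'   sequences keyed by lncRNA id.
#' @param e_max E-value gate (default 0.01).
#' @param background base frequencies.
#' @return object of class `tf_network`: list with `edges` (data frame
#'   `tf`, `lncrna_id`), `hits` (per-hit data frame with offset, strand,
#'   score, e_value), and `summary` (n_tfs, n_lncrnas, n_edges counting
#'   only connected nodes).
#' @export
build_tf_lncrna_network <- function(pfms, promoters, e_max = 0.01,
                                    background = rep(0.25, 4)) {
  promoters <- unlist(promoters)
  if (length(promoters) == 0L || length(pfms) == 0L) {
    hits <- data.frame(tf = character(0), lncrna_id = character(0),
                       offset = integer(0), strand = character(0),
                       score = numeric(0), e_value = numeric(0),
                       stringsAsFactors = FALSE)
    return(structure(
      list(edges = hits[, c("tf", "lncrna_id")], hits = hits,
           summary = c(n_tfs = 0L, n_lncrnas = 0L, n_edges = 0L),
           e_max = e_max),
      class = "tf_network"))
  }
  if (is.null(names(promoters)) || anyDuplicated(names(promoters)))
    stop_domain("'promoters' must be uniquely named by lncRNA id")
  hit_rows <- list()
  for (p in pfms) {
    w_mat <- pfm_log_odds(p, background)
    width <- ncol(w_mat)
    n_pos <- sum(pmax(nchar(promoters) - width + 1L, 0L)) * 2L
    if (n_pos == 0L) next
    dist <- pwm_score_distribution(w_mat, background)
    for (lid in names(promoters)) {
      if (nchar(promoters[[lid]]) < width) next
      sc <- scan_promoter(w_mat, promoters[[lid]], both_strands = TRUE,
                          background = background)
      ev <- tail_prob_at(dist, sc$score) * n_pos
      keep <- ev < e_max
      if (any(keep)) {
        h <- sc[keep, , drop = FALSE]
        h$e_value <- ev[keep]
        h$tf <- p$tf_name
        h$lncrna_id <- lid
        hit_rows[[length(hit_rows) + 1L]] <- h
      }
    }
  }
  if (length(hit_rows) > 0L) {
    hits <- do.call(rbind, hit_rows)
    hits <- hits[, c("tf", "lncrna_id", "offset", "strand", "score",
                     "e_value")]
    edges <- unique(hits[, c("tf", "lncrna_id")])
    edges <- edges[order(edges$tf, edges$lncrna_id), , drop = FALSE]
    rownames(edges) <- rownames(hits) <- NULL
  } else {
    hits <- data.frame(tf = character(0), lncrna_id = character(0),
                       offset = integer(0), strand = character(0),
                       score = numeric(0), e_value = numeric(0),
                       stringsAsFactors = FALSE)
    edges <- hits[, c("tf", "lncrna_id")]
  }
  structure(
    list(edges = edges, hits = hits,
         summary = c(n_tfs = length(unique(edges$tf)),
                     n_lncrnas = length(unique(edges$lncrna_id)),
                     n_edges = nrow(edges)),
         e_max = e_max),
    class = "tf_network")
}

#' @export
print.tf_network <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "TF-lncRNA network: %d TFs and %d correlated lncRNAs connected by %d edges (E < %g)\n",
    s["n_tfs"], s["n_lncrnas"], s["n_edges"], x$e_max))
  invisible(x)
}

#' Hypergeometric enrichment of a TF's targets in a co-expressed gene set
#'
#' Upper-tail hypergeometric probability that the overlap between the
#' genes co-expressed with a lncRNA and the target genes of a TF is at
#' least as large as observed, given the gene universe.
#'
#' @param coexpr_genes genes co-expressed with the lncRNA.
#' @param tf_target_genes target gene set of the TF.
#' @param universe_size number of genes in the universe (>= union size).
#' @return list with `overlap` (gene ids), `k`, `p`.
#' @export
tf_target_enrichment <- function(coexpr_genes, tf_target_genes,
                                 universe_size) {
  check_number(universe_size, "universe_size", lower = 1, integer = TRUE)
  coexpr_genes <- unique(coexpr_genes)
  tf_target_genes <- unique(tf_target_genes)
  if (length(coexpr_genes) > universe_size ||
      length(tf_target_genes) > universe_size)
    stop_domain("gene sets larger than the universe")
  ov <- intersect(coexpr_genes, tf_target_genes)
  p <- hypergeom_pvalue(length(ov), length(tf_target_genes),
                        length(coexpr_genes), universe_size)
  list(overlap = sort(ov), k = length(ov), p = p)
}

#' Build the lncRNA-TF-mRNA ternary (trans-regulation) network
#'
#' A triple (lncRNA, TF, gene) is emitted when the TF has a motif hit in
#' the lncRNA promoter, the gene is co-expressed with the lncRNA at
#' `|r| >= r_min & q <= q_max`, the gene is a target of the TF, and the
#' (lncRNA, TF) pair passed the hypergeometric enrichment gate
#' (`p < enrich_p_max & q < enrich_q_max`, BH over all scanned pairs).
#'
#' @param cnc_edges a [build_cnc()] result (or any data frame with
#'   `nc_id`, `coding_id`, `r`, `q`).
#' @param tf_lnc_edges `edges` of a [build_tf_lncrna_network()] result.
#' @param tf_target_map named list: TF name -> character vector of
#'   target gene ids.
#' @param universe_size gene universe size for the enrichment gate.
#' @param r_min,q_max co-expression gate for triples (defaults 0.9,
#'   0.05).
#' @param enrich_p_max,enrich_q_max enrichment gate (defaults 0.01,
#'   0.01).
#' @return object of class `ternary_network`: list with `triples` (data
#'   frame `lncrna_id`, `tf`, `gene_id`), `enrichment` (per tested
#'   (lncRNA, TF) pair: overlap size, p, q, passed), and `summary`
#'   (n_lncrnas, n_tfs, n_genes over the triples).
#' @export
build_ternary_network <- function(cnc_edges, tf_lnc_edges, tf_target_map,
                                  universe_size, r_min = 0.9,
                                  q_max = 0.05, enrich_p_max = 0.01,
                                  enrich_q_max = 0.01) {
  coexpr <- cnc_edges[abs(cnc_edges$r) >= r_min & cnc_edges$q <= q_max, ,
                      drop = FALSE]
  coexpr_by_lnc <- split(coexpr$coding_id, coexpr$nc_id)
  ## enrichment gate per (lncRNA, TF) pair with a promoter hit
  enr_rows <- list()
  for (i in seq_len(nrow(tf_lnc_edges))) {
    tf <- tf_lnc_edges$tf[i]; lnc <- tf_lnc_edges$lncrna_id[i]
    genes <- coexpr_by_lnc[[lnc]] %||% character(0)
    targets <- tf_target_map[[tf]] %||% character(0)
    e <- tf_target_enrichment(genes, targets, universe_size)
    enr_rows[[i]] <- data.frame(lncrna_id = lnc, tf = tf, k = e$k,
                                p = e$p, stringsAsFactors = FALSE)
  }
  if (length(enr_rows) == 0L) {
    enrichment <- data.frame(lncrna_id = character(0), tf = character(0),
                             k = integer(0), p = numeric(0),
                             q = numeric(0), passed = logical(0),
                             stringsAsFactors = FALSE)
  } else {
    enrichment <- do.call(rbind, enr_rows)
    enrichment$q <- bh_adjust(enrichment$p)
    enrichment$passed <- enrichment$p < enrich_p_max &
      enrichment$q < enrich_q_max
  }
  rows <- list()
  for (i in seq_len(nrow(enrichment))) {
    if (!enrichment$passed[i]) next
    lnc <- enrichment$lncrna_id[i]; tf <- enrichment$tf[i]
    genes <- intersect(coexpr_by_lnc[[lnc]] %||% character(0),
                       tf_target_map[[tf]] %||% character(0))
    if (length(genes) > 0)
      rows[[length(rows) + 1L]] <- data.frame(
        lncrna_id = lnc, tf = tf, gene_id = sort(genes),
        stringsAsFactors = FALSE)
  }
  triples <- if (length(rows) > 0L) do.call(rbind, rows) else
    data.frame(lncrna_id = character(0), tf = character(0),
               gene_id = character(0), stringsAsFactors = FALSE)
  triples <- triples[order(triples$lncrna_id, triples$tf,
                           triples$gene_id), , drop = FALSE]
  rownames(triples) <- NULL
  structure(
    list(triples = triples, enrichment = enrichment,
         summary = c(n_lncrnas = length(unique(triples$lncrna_id)),
                     n_tfs = length(unique(triples$tf)),
                     n_genes = length(unique(triples$gene_id)))),
    class = "ternary_network")
}

#' @export
print.ternary_network <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "lncRNA-TF-gene network: %d lncRNAs, %d TFs, and %d correlated genes (%d triples)\n",
    s["n_lncrnas"], s["n_tfs"], s["n_genes"], nrow(x$triples)))
  invisible(x)
}
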