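## Independent brute-force oracles and small fixture builders used
## across the suite. The oracles deliberately avoid the package's code
## paths: explicit double loops, per-base integer sets, and literal
## string searches.

## Benjamini-Hochberg by direct evaluation of q_(i) = min_{j>=i}
## p_(j) m / j on the sorted vector (double loop).
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(m)
  for (i in seq_len(m)) {
    best <- Inf
    for (j in i:m) best <- min(best, ps[j] * m / j)
    q[i] <- min(best, 1)
  }
  out <- numeric(m)
  out[o] <- q
  out
}

## Exact upper hypergeometric tail by combinatorial summation (no
## dhyper): P(X >= k) = sum_i C(K,i) C(N-K,n-i) / C(N,n).
oracle_hyper_tail <- function(k, K, n, N) {
  if (k == 0) return(1)
  tot <- 0
  for (i in k:min(K, n))
    tot <- tot + choose(K, i) * choose(N - K, n - i)
  tot / choose(N, n)
}

## Per-base integer sets for a transcript record.
oracle_bases <- function(start, end) if (start < end) start:(end - 1) else integer(0)
oracle_exon_bases <- function(rec)
  unlist(lapply(seq_len(nrow(rec$exons)), function(i)
    oracle_bases(rec$exons[i, 1], rec$exons[i, 2])))

## Category call for one lncRNA against coding genes, using explicit
## base sets instead of interval arithmetic.
oracle_classify <- function(lnc, coding, bidir_window = 1000) {
  labels <- character(0)
  lnc_span <- oracle_bases(lnc$start, lnc$end)
  lnc_ex <- oracle_exon_bases(lnc)
  for (g in coding) {
    if (g$chrom != lnc$chrom) next
    g_span <- oracle_bases(g$start, g$end)
    shared_span <- intersect(lnc_span, g_span)
    same <- g$strand == lnc$strand
    if (length(shared_span) > 0) {
      shared_ex <- intersect(lnc_ex, oracle_exon_bases(g))
      lab <- if (same) {
        if (length(shared_ex) > 0) "exon_overlapping" else "intron_overlapping"
      } else {
        if (length(shared_ex) > 0) "natural_antisense" else "intron_antisense"
      }
      labels <- union(labels, lab)
    } else if (!same) {
      t_l <- if (lnc$strand == "+") lnc$start else lnc$end
      t_g <- if (g$strand == "+") g$start else g$end
      plus_tss <- if (lnc$strand == "+") t_l else t_g
      minus_tss <- if (lnc$strand == "+") t_g else t_l
      if (abs(t_l - t_g) < bidir_window && plus_tss >= minus_tss)
        labels <- union(labels, "bidirectional")
    }
  }
  if (length(labels) == 0) labels <- "intergenic"
  sort(labels)
}

## All-pairs cis scan by direct arithmetic.
oracle_cis <- function(lnc, coding, window = 300000) {
  hits <- list()
  for (g in coding) {
    if (g$chrom != lnc$chrom) next
    d <- if (min(lnc$end, g$end) > max(lnc$start, g$start)) 0
    else if (g$start >= lnc$end) g$start - lnc$end
    else lnc$start - g$end
    if (d < window)
      hits[[length(hits) + 1]] <- data.frame(gene_id = g$id,
                                            distance_bp = d)
  }
  if (length(hits) == 0)
    return(data.frame(gene_id = character(0), distance_bp = numeric(0)))
  out <- do.call(rbind, hits)
  out[order(out$distance_bp, out$gene_id), , drop = FALSE]
}

## Literal-string seed-site oracle: builds the four site strings for a
## miRNA and scans for them with precedence 8mer > 7mer-m8 > 7mer-A1 >
## 6mer at each core locus.
oracle_seed_sites <- function(mirna, target, circular = FALSE) {
  comp <- c(A = "U", C = "G", G = "C", U = "A")
  mc <- strsplit(mirna, "")[[1]]
  rc <- function(x) paste(rev(unname(comp[strsplit(x, "")[[1]]])),
                          collapse = "")
  core <- rc(paste(mc[2:7], collapse = ""))
  m8 <- unname(comp[mc[8]])
  L <- nchar(target)
  ext <- if (circular) paste0(target, substr(target, 1, 7)) else target
  ## find all (overlapping) core matches with start within the original
  starts <- c()
  for (s in 1:(nchar(ext) - 5)) {
    if (substr(ext, s, s + 5) == core && s <= L) starts <- c(starts, s)
  }
  rows <- list()
  for (s in starts) {
    prev <- if (s > 1) substr(ext, s - 1, s - 1) else
      if (circular) substr(target, L, L) else ""
    nxt <- if (s + 6 <= nchar(ext)) substr(ext, s + 6, s + 6) else
      if (circular) substr(target, (s + 5) %% L + 1, (s + 5) %% L + 1) else ""
    has_m8 <- prev == m8
    has_a1 <- nxt == "A"
    type <- if (has_m8 && has_a1) "8mer" else if (has_m8) "7mer_m8"
    else if (has_a1) "7mer_A1" else "6mer"
    off <- (s - 1) - as.integer(has_m8)
    if (off < 0) {
      if (circular) off <- off %% L
      else { type <- if (has_a1) "7mer_A1" else "6mer"; off <- s - 1 }
    }
    rows[[length(rows) + 1]] <- data.frame(offset = off, site_type = type,
                                           stringsAsFactors = FALSE)
  }
  if (length(rows) == 0)
    return(data.frame(offset = integer(0), site_type = character(0)))
  out <- do.call(rbind, rows)
  out[order(out$offset), , drop = FALSE]
}

## random transcript fixture on a compact locus (dense overlaps)
random_transcripts <- function(n_lnc, n_gene, span = 60000, chroms = c("c1", "c2")) {
  mk <- function(id, type) {
    chrom <- sample(chroms, 1)
    start <- sample(0:span, 1)
    len <- sample(500:8000, 1)
    end <- start + len
    strand <- sample(c("+", "-"), 1)
    n_ex <- sample(1:3, 1)
    bounds <- sort(sample(seq(start, end, length.out = 2 * n_ex + 2)[
      2:(2 * n_ex + 1)]))
    exons <- matrix(round(bounds), ncol = 2, byrow = TRUE)
    exons[1, 1] <- start
    exons[nrow(exons), 2] <- end
    bad <- exons[, 1] >= exons[, 2]
    if (any(bad)) exons <- matrix(c(start, end), ncol = 2)
    transcript_record(id, id, type, chrom, start, end, strand,
                      exons = exons)
  }
  list(lncs = lapply(sprintf("L%03d", seq_len(n_lnc)), mk, type = "lncRNA"),
       genes = lapply(sprintf("G%03d", seq_len(n_gene)), mk, type = "mRNA"))
}

## small informative PFM fixture
informative_pfm <- function(name, consensus) {
  bases <- c("A", "C", "G", "T")
  w <- nchar(consensus)
  counts <- matrix(5, 4, w, dimnames = list(bases, NULL))
  idx <- match(strsplit(consensus, "")[[1]], bases)
  counts[cbind(idx, seq_len(w))] <- 85
  pfm(name, counts)
}

## small study config used by several files (fast to simulate);
## overrides win over the small-scale defaults
small_config <- function(seed = 1, ...) {
  args <- utils::modifyList(
    list(seed = seed, n_mrna = 200, n_lncrna = 40, n_circrna = 20,
         n_coexpr_pairs = 4, n_mirna = 4, n_tf = 3),
    list(...))
  do.call(sim_config, args)
}
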