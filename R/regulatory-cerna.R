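## Competing endogenous RNA (ceRNA) prediction: canonical miRNA seed
## sites (TargetScan site types 6mer, 7mer-A1, 7mer-m8, 8mer; no GU
## wobble) located on transcript sequences, with back-splice-junction
## wraparound for circRNAs, and the tripartite
## lncRNA/circRNA - miRNA - mRNA network from shared sites.

SITE_TYPES <- c("6mer", "7mer_A1", "7mer_m8", "8mer")
SITE_LENGTH <- c("6mer" = 6L, "7mer_A1" = 7L, "7mer_m8" = 7L, "8mer" = 8L)

#' @noRd
check_rna_alphabet <- function(seq, what) {
  if (grepl("[^ACGU]", seq))
    stop_domain(sprintf("'%s' must be an RNA sequence over A, C, G, U",
                        what))
}

#' Find canonical miRNA seed-match sites on a target sequence
#'
#' Locates target sites complementary to the miRNA seed (positions
#' 2-7/2-8 from the miRNA 5' end, Watson-Crick only): a 6mer core match
#' to positions 2-7, optionally extended by a match to position 8
#' (7mer-m8) and/or an adenosine across from position 1 (7mer-A1);
#' both extensions together form an 8mer. Each core locus is reported
#' once with its strongest type. Circular targets are scanned across the
#' back-splice junction by wrapping the first 7 bases.
#'
#' @param mirna_sequence miRNA, 5'->3' RNA string, length >= 8.
#' @param target_sequence target RNA string (mRNA 3'UTR, lncRNA, or the
#'   linearized circRNA sequence).
#' @param circular scan with wraparound (circRNA back-splice junction).
#' @return data frame with `offset` (0-based start of the full site on
#'   the target; may wrap for circular targets), `site_type`, and
#'   `site_length`; ordered by offset.
#' @export
find_seed_sites <- function(mirna_sequence, target_sequence,
                            circular = FALSE) {
  check_rna_alphabet(mirna_sequence, "mirna_sequence")
  check_rna_alphabet(target_sequence, "target_sequence")
  if (nchar(mirna_sequence) < 8L)
    stop_domain("miRNA must be at least 8 nt")
  L <- nchar(target_sequence)
  empty <- data.frame(offset = integer(0), site_type = character(0),
                      site_length = integer(0), stringsAsFactors = FALSE)
  if (L < 6L) return(empty)
  m <- strsplit(mirna_sequence, "", fixed = TRUE)[[1L]]
  core <- revcomp_rna(paste(m[2:7], collapse = ""))   # matches seed 2-7
  m8_base <- unname(COMPLEMENT[m[8L]])                # target base pairing m8
  ext <- if (circular) {
    paste0(target_sequence,
           substr(target_sequence, 1L, min(7L, L)))
  } else target_sequence
  tchars <- strsplit(ext, "", fixed = TRUE)[[1L]]
  hits <- gregexpr(core, ext, fixed = TRUE)[[1L]]
  if (hits[1L] == -1L) return(empty)
  ## overlapping matches: gregexpr is non-overlapping, rescan manually
  starts <- integer(0)
  from <- 1L
  while (TRUE) {
    i <- regexpr(core, substr(ext, from, nchar(ext)), fixed = TRUE)
    if (i == -1L) break
    starts <- c(starts, from + i - 1L)
    from <- from + i
  }
  ## core start positions on the original coordinate system (1-based)
  starts <- starts[starts <= L]
  rows <- list()
  for (s in starts) {
    ## m8: target base immediately 5' of the core pairs miRNA position 8
    prev <- if (s > 1L) tchars[s - 1L] else if (circular) tchars[L] else NA
    has_m8 <- !is.na(prev) && prev == m8_base
    ## A1: target base immediately 3' of the core is an A
    nxt_i <- s + 6L
    nxt <- if (nxt_i <= length(tchars)) tchars[nxt_i] else
      if (circular) tchars[((nxt_i - 1L) %% L) + 1L] else NA
    has_a1 <- !is.na(nxt) && nxt == "A"
    type <- if (has_m8 && has_a1) "8mer" else if (has_m8) "7mer_m8" else
      if (has_a1) "7mer_A1" else "6mer"
    start0 <- (s - 1L) - as.integer(has_m8)         # 0-based site start
    if (start0 < 0L) {
      if (!circular) {type <- if (has_a1) "7mer_A1" else "6mer"; start0 <- s - 1L}
      else start0 <- start0 %% L
    }
    rows[[length(rows) + 1L]] <- data.frame(
      offset = start0, site_type = type,
      site_length = SITE_LENGTH[[type]], stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$offset), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Seed sites for many miRNAs against many targets
#'
#' Convenience wrapper over [find_seed_sites()].
#'
#' @param mirnas named character vector of miRNA sequences.
#' @param targets named character vector of target RNA sequences.
#' @param circular_ids ids in `targets` to scan with wraparound.
#' @return data frame `mirna_id`, `target_id`, `offset`, `site_type`.
#' @export
seed_site_table <- function(mirnas, targets, circular_ids = character(0)) {
  rows <- list()
  for (mid in names(mirnas)) {
    for (tid in names(targets)) {
      s <- find_seed_sites(mirnas[[mid]], targets[[tid]],
                           circular = tid %in% circular_ids)
      if (nrow(s) > 0L)
        rows[[length(rows) + 1L]] <- data.frame(
          mirna_id = mid, target_id = tid, offset = s$offset,
          site_type = s$site_type, stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L)
    return(data.frame(mirna_id = character(0), target_id = character(0),
                      offset = integer(0), site_type = character(0),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Build the ceRNA network from shared seed sites
#'
#' A triple (noncoding RNA, miRNA, mRNA) is emitted when the same miRNA
#' has at least one seed site on both the noncoding transcript (lncRNA
#' or circRNA) and the mRNA, and both transcripts are differentially
#' expressed. The network is exported as noncoding-miRNA and miRNA-mRNA
#' edges (the tripartite structure).
#'
#' @param de_nc ids of DE lncRNAs/circRNAs.
#' @param de_mrna ids of DE mRNAs.
#' @param seed_sites a [seed_site_table()]-shaped data frame
#'   (`mirna_id`, `target_id`, ...).
#' @return object of class `cerna_network`: list with `triples` (data
#'   frame `nc_id`, `mirna_id`, `mrna_id`, sorted lexicographically) and
#'   `edges` (data frame `from`, `to`, `relation` with relations
#'   `nc_mirna` and `mirna_mrna`).
#' @export
build_cerna <- function(de_nc, de_mrna, seed_sites) {
  rows <- list()
  for (mid in unique(seed_sites$mirna_id)) {
    tg <- unique(seed_sites$target_id[seed_sites$mirna_id == mid])
    ncs <- sort(intersect(tg, de_nc))
    mrs <- sort(intersect(tg, de_mrna))
    if (length(ncs) > 0L && length(mrs) > 0L)
      rows[[length(rows) + 1L]] <- expand.grid(
        nc_id = ncs, mirna_id = mid, mrna_id = mrs,
        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  }
  triples <- if (length(rows) > 0L) do.call(rbind, rows) else
    data.frame(nc_id = character(0), mirna_id = character(0),
               mrna_id = character(0), stringsAsFactors = FALSE)
  triples <- triples[order(triples$nc_id, triples$mirna_id,
                           triples$mrna_id), , drop = FALSE]
  rownames(triples) <- NULL
  e1 <- unique(data.frame(from = triples$nc_id, to = triples$mirna_id,
                          relation = rep("nc_mirna", nrow(triples)),
                          stringsAsFactors = FALSE))
  e2 <- unique(data.frame(from = triples$mirna_id, to = triples$mrna_id,
                          relation = rep("mirna_mrna", nrow(triples)),
                          stringsAsFactors = FALSE))
  edges <- rbind(e1, e2)
  edges <- edges[order(edges$relation, edges$from, edges$to), ,
                 drop = FALSE]
  rownames(edges) <- NULL
  structure(list(triples = triples, edges = edges),
            class = "cerna_network")
}

#' @export
print.cerna_network <- function(x, ...) {
  cat(sprintf(
    "ceRNA network: %d triples (%d noncoding, %d miRNAs, %d mRNAs)\n",
    nrow(x$triples), length(unique(x$triples$nc_id)),
    length(unique(x$triples$mirna_id)),
    length(unique(x$triples$mrna_id))))
  invisible(x)
}
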