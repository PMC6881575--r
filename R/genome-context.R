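## Genomic context of lncRNAs: six-category positional classification
## relative to protein-coding genes (with multi-label support and Venn
## counts) and cis-candidate coding genes within a fixed window.
##
## Internal coordinates are 0-based half-open; GFF3 I/O converts at the
## boundary.

LNC_CATEGORIES <- c("exon_overlapping", "intron_overlapping",
                    "natural_antisense", "intron_antisense",
                    "bidirectional", "intergenic")

#' Construct a transcript record
#'
#' Stranded genomic model of one transcript (coding gene, lncRNA or
#' circRNA) with its exon structure, in 0-based half-open coordinates.
#'
#' @param id transcript identifier (unique within a set).
#' @param gene_id gene-level identifier.
#' @param rna_type one of `"mRNA"`, `"lncRNA"`, `"circRNA"`.
#' @param chrom chromosome name.
#' @param start,end transcript span, 0-based half-open, `start < end`.
#' @param strand `"+"` or `"-"`.
#' @param exons two-column matrix of exon (start, end) pairs, 0-based
#'   half-open, sorted, pairwise disjoint, contained in the span.
#'   Defaults to a single exon covering the span.
#' @param is_circular `TRUE` for circRNAs (back-spliced transcripts).
#' @return an object of class `transcript`.
#' @export
transcript_record <- function(id, gene_id, rna_type, chrom, start, end,
                              strand, exons = NULL, is_circular = FALSE) {
  check_number(start, "start", lower = 0, integer = TRUE)
  check_number(end, "end", integer = TRUE)
  if (start >= end) stop_domain("'start' must be < 'end'")
  if (!strand %in% c("+", "-"))
    stop_domain("'strand' must be '+' or '-'")
  if (!rna_type %in% c("mRNA", "lncRNA", "circRNA"))
    stop_domain("'rna_type' must be mRNA/lncRNA/circRNA")
  if (is.null(exons)) exons <- matrix(c(start, end), ncol = 2)
  exons <- matrix(as.numeric(exons), ncol = 2)
  if (any(exons[, 1] >= exons[, 2]))
    stop_domain("exon starts must be < exon ends")
  o <- order(exons[, 1])
  exons <- exons[o, , drop = FALSE]
  if (nrow(exons) > 1 && any(exons[-1, 1] < exons[-nrow(exons), 2]))
    stop_domain("exons must be pairwise disjoint")
  if (exons[1, 1] < start || exons[nrow(exons), 2] > end)
    stop_domain("exons must be contained in [start, end)")
  colnames(exons) <- c("start", "end")
  structure(
    list(id = id, gene_id = gene_id, rna_type = rna_type, chrom = chrom,
         start = start, end = end, strand = strand, exons = exons,
         is_circular = isTRUE(is_circular)),
    class = "transcript")
}

#' @export
print.transcript <- function(x, ...) {
  cat(sprintf("%s [%s] %s:%s-%s(%s), %d exon(s)%s\n", x$id, x$rna_type,
              x$chrom, format(x$start, scientific = FALSE),
              format(x$end, scientific = FALSE), x$strand, nrow(x$exons),
              if (x$is_circular) ", circular" else ""))
  invisible(x)
}

#' Summarize a list of transcript records as a data frame
#' @param records list of [transcript_record()] objects.
#' @return data frame with one row per transcript (exon structure is
#'   collapsed to a count).
#' @export
transcripts_df <- function(records) {
  do.call(rbind, lapply(records, function(r) data.frame(
    id = r$id, gene_id = r$gene_id, rna_type = r$rna_type,
    chrom = r$chrom, start = r$start, end = r$end, strand = r$strand,
    n_exons = nrow(r$exons), is_circular = r$is_circular,
    stringsAsFactors = FALSE)))
}

## base-overlap length of [a1,a2) and [b1,b2)
#' @noRd
overlap_len <- function(a1, a2, b1, b2) max(0, min(a2, b2) - max(a1, b1))

#' @noRd
exon_exon_overlap <- function(a, b) {
  for (i in seq_len(nrow(a$exons)))
    for (j in seq_len(nrow(b$exons)))
      if (overlap_len(a$exons[i, 1], a$exons[i, 2],
                      b$exons[j, 1], b$exons[j, 2]) > 0) return(TRUE)
  FALSE
}

#' @noRd
tss_of <- function(x) if (x$strand == "+") x$start else x$end

#' Classify one lncRNA against a set of coding genes
#'
#' Assigns the positional categories of the lncRNA with respect to every
#' protein-coding gene on the same chromosome:
#' \describe{
#'   \item{exon_overlapping}{exonic base overlap on the same strand}
#'   \item{intron_overlapping}{same-strand span overlap with no exonic
#'     base overlap (the shared bases fall in introns)}
#'   \item{natural_antisense}{exonic base overlap on the opposite strand}
#'   \item{intron_antisense}{opposite-strand span overlap confined to
#'     introns}
#'   \item{bidirectional}{no overlap, but the two 5' ends lie within
#'     `bidir_window_bp` in divergent (back-to-back) orientation on
#'     opposite strands}
#'   \item{intergenic}{none of the above; exclusive of all other labels}
#' }
#' A lncRNA can carry several labels (one per qualifying gene); the
#' `primary` label is the first match in the precedence order above.
#'
#' @param lnc a `transcript` with `rna_type == "lncRNA"`.
#' @param coding list of coding-gene `transcript` records.
#' @param bidir_window_bp divergent-promoter window (default 1000 bp).
#' @return list with `lncrna_id`, `labels` (character vector) and
#'   `primary`.
#' @export
classify_lncrna <- function(lnc, coding, bidir_window_bp = 1000) {
  stopifnot(inherits(lnc, "transcript"))
  if (lnc$rna_type != "lncRNA")
    stop_domain("'lnc' must have rna_type lncRNA")
  labels <- character(0)
  for (g in coding) {
    if (g$chrom != lnc$chrom) next
    span_ov <- overlap_len(lnc$start, lnc$end, g$start, g$end) > 0
    same <- g$strand == lnc$strand
    if (span_ov) {
      exonic <- exon_exon_overlap(lnc, g)
      lab <- if (same) {
        if (exonic) "exon_overlapping" else "intron_overlapping"
      } else {
        if (exonic) "natural_antisense" else "intron_antisense"
      }
      labels <- union(labels, lab)
    } else if (!same) {
      ## divergent: the + strand partner sits to the right of (or at)
      ## the - strand partner's TSS, transcribing away from it
      t_l <- tss_of(lnc); t_g <- tss_of(g)
      plus_tss <- if (lnc$strand == "+") t_l else t_g
      minus_tss <- if (lnc$strand == "+") t_g else t_l
      if (abs(t_l - t_g) < bidir_window_bp && plus_tss >= minus_tss)
        labels <- union(labels, "bidirectional")
    }
  }
  if (length(labels) == 0L) labels <- "intergenic"
  labels <- LNC_CATEGORIES[LNC_CATEGORIES %in% labels]
  list(lncrna_id = lnc$id, labels = labels, primary = labels[1L])
}

#' Classify all lncRNAs and tabulate category and Venn counts
#'
#' @param lncs list of lncRNA `transcript` records.
#' @param coding list of coding-gene `transcript` records.
#' @param bidir_window_bp see [classify_lncrna()].
#' @return object of class `lnc_classification`: list with `calls` (one
#'   [classify_lncrna()] result per lncRNA), `counts` (every label
#'   occurrence per category), `percent` (of all classified lncRNAs),
#'   and `venn` (named counts keyed by the exact label set, `+`-joined).
#' @export
classify_all <- function(lncs, coding, bidir_window_bp = 1000) {
  calls <- lapply(lncs, classify_lncrna, coding = coding,
                  bidir_window_bp = bidir_window_bp)
  names(calls) <- vapply(calls, `[[`, "", "lncrna_id")
  counts <- stats::setNames(integer(length(LNC_CATEGORIES)), LNC_CATEGORIES)
  for (cl in calls) counts[cl$labels] <- counts[cl$labels] + 1L
  venn_keys <- vapply(calls, function(cl) paste(cl$labels, collapse = "+"), "")
  venn <- table(venn_keys)
  structure(
    list(calls = calls,
         counts = counts,
         percent = 100 * counts / max(length(calls), 1L),
         venn = stats::setNames(as.integer(venn), names(venn))),
    class = "lnc_classification")
}

#' @export
print.lnc_classification <- function(x, ...) {
  cat(sprintf("lncRNA positional classification (%d lncRNAs)\n",
              length(x$calls)))
  for (cat_ in names(x$counts))
    cat(sprintf("  %-18s %5d (%.1f%%)\n", cat_, x$counts[[cat_]],
                x$percent[[cat_]]))
  invisible(x)
}

#' Cis-candidate coding genes within a genomic window
#'
#' Returns every coding gene on the same chromosome whose nearest-edge
#' gap to the lncRNA is below `window_bp` (overlapping genes count as
#' distance 0), the standard operationalization of "adjacent genes less
#' than 300 kb upstream or downstream".
#'
#' @param lnc a lncRNA `transcript`.
#' @param coding list of coding-gene `transcript` records.
#' @param window_bp window in bp (default 300000).
#' @return data frame with columns `lncrna_id`, `gene_id`,
#'   `distance_bp`, `relative_position` (upstream/downstream relative to
#'   the lncRNA strand, or overlapping), sorted by distance then gene id.
#' @export
cis_neighbors <- function(lnc, coding, window_bp = 300000) {
  stopifnot(inherits(lnc, "transcript"))
  rows <- list()
  for (g in coding) {
    if (g$chrom != lnc$chrom) next
    if (overlap_len(lnc$start, lnc$end, g$start, g$end) > 0) {
      d <- 0; pos <- "overlapping"
    } else if (g$start >= lnc$end) {
      d <- g$start - lnc$end
      pos <- if (lnc$strand == "+") "downstream" else "upstream"
    } else {
      d <- lnc$start - g$end
      pos <- if (lnc$strand == "+") "upstream" else "downstream"
    }
    if (d < window_bp)
      rows[[length(rows) + 1L]] <- data.frame(
        lncrna_id = lnc$id, gene_id = g$id, distance_bp = d,
        relative_position = pos, stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L)
    return(data.frame(lncrna_id = character(0), gene_id = character(0),
                      distance_bp = numeric(0),
                      relative_position = character(0),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out[order(out$distance_bp, out$gene_id), , drop = FALSE]
}
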