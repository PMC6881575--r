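## File-format adapters. Expression matrices travel as TSV with group
## labels embedded in the header ("sample:group"); annotations as GFF3
## (1-based inclusive on disk, 0-based half-open in memory); sequences
## as FASTA via Biostrings; PFMs as MEME-motif-format text; term tables
## as two/three-column TSV; truth as JSON.

#' Write an expression matrix to TSV
#'
#' Header: `probe_id`, `type`, then one `sample:group` column per
#' sample. Values are written at full precision.
#'
#' @param mat an [expression_matrix()].
#' @param path output file.
#' @export
write_expression_tsv <- function(mat, path) {
  stopifnot(inherits(mat, "expr_matrix"))
  header <- c("probe_id", "type",
              paste(names(mat$group), mat$group, sep = ":"))
  df <- data.frame(probe_id = rownames(mat$values),
                   type = unname(mat$rna_type),
                   mat$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(header, collapse = "\t"), con)
  utils::write.table(format(df, digits = 17, trim = TRUE,
                            scientific = FALSE),
                     con, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read an expression matrix from TSV
#'
#' @param path file written by [write_expression_tsv()] (or matching
#'   its contract).
#' @return an [expression_matrix()].
#' @export
read_expression_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 4L || names(df)[1L] != "probe_id" ||
      names(df)[2L] != "type")
    stop_domain("expression TSV must start with columns probe_id, type")
  sample_cols <- names(df)[-(1:2)]
  parts <- strsplit(sample_cols, ":", fixed = TRUE)
  if (any(lengths(parts) != 2L))
    stop_domain("sample columns must be named 'sample:group'")
  sample_ids <- vapply(parts, `[[`, "", 1L)
  group <- vapply(parts, `[[`, "", 2L)
  vals <- as.matrix(df[, -(1:2), drop = FALSE])
  if (anyNA(vals)) {
    bad <- which(is.na(vals), arr.ind = TRUE)[1L, ]
    stop_domain(sprintf(
      "missing/non-numeric intensity at probe '%s', sample '%s'",
      df$probe_id[bad[1L]], sample_ids[bad[2L]]))
  }
  if (any(vals <= 0)) {
    bad <- which(vals <= 0, arr.ind = TRUE)[1L, ]
    stop_domain(sprintf(
      "non-positive intensity at probe '%s', sample '%s'",
      df$probe_id[bad[1L]], sample_ids[bad[2L]]))
  }
  if (anyDuplicated(df$probe_id))
    stop_domain("duplicated probe_id: ",
                df$probe_id[anyDuplicated(df$probe_id)])
  if (!all(df$type %in% c("mRNA", "lncRNA", "circRNA")))
    stop_domain("unknown rna_type in 'type' column")
  expression_matrix(vals, df$type, group, probe_ids = df$probe_id,
                    sample_ids = sample_ids)
}

#' Write transcript records to GFF3
#'
#' Each transcript becomes a `transcript` feature (attributes `ID`,
#' `gene_id`, `rna_type`, `is_circular`) with child `exon` features.
#' Internal 0-based half-open coordinates are converted to the GFF3
#' 1-based inclusive convention.
#'
#' @param records list of [transcript_record()]s.
#' @param path output file.
#' @export
write_gff3 <- function(records, path) {
  n_ex <- vapply(records, function(r) nrow(r$exons), 0L)
  tx <- data.frame(
    chrom = vapply(records, `[[`, "", "chrom"),
    start = vapply(records, `[[`, 0, "start") + 1,
    end = vapply(records, `[[`, 0, "end"),
    strand = vapply(records, `[[`, "", "strand"),
    ID = vapply(records, `[[`, "", "id"),
    gene_id = vapply(records, `[[`, "", "gene_id"),
    rna_type = vapply(records, `[[`, "", "rna_type"),
    is_circular_rna = as.character(
      vapply(records, `[[`, TRUE, "is_circular")),
    stringsAsFactors = FALSE)
  ex_start <- unlist(lapply(records, function(r) r$exons[, 1])) + 1
  ex_end <- unlist(lapply(records, function(r) r$exons[, 2]))
  ex <- data.frame(
    chrom = rep(tx$chrom, n_ex),
    strand = rep(tx$strand, n_ex),
    parent = rep(tx$ID, n_ex),
    gene_id = rep(tx$gene_id, n_ex),
    rna_type = rep(tx$rna_type, n_ex),
    stringsAsFactors = FALSE)
  ex$ID <- paste0(ex$parent, ".exon",
                  unlist(lapply(n_ex, seq_len)))
  gr_tx <- GenomicRanges::GRanges(
    tx$chrom, IRanges::IRanges(tx$start, tx$end), strand = tx$strand,
    type = "transcript", ID = tx$ID, gene_id = tx$gene_id,
    rna_type = tx$rna_type, is_circular_rna = tx$is_circular_rna,
    Parent = IRanges::CharacterList(vector("list", nrow(tx))))
  gr_ex <- GenomicRanges::GRanges(
    ex$chrom, IRanges::IRanges(ex_start, ex_end), strand = ex$strand,
    type = "exon", ID = ex$ID, gene_id = ex$gene_id,
    rna_type = ex$rna_type, is_circular_rna = "NA",
    Parent = IRanges::CharacterList(as.list(ex$parent)))
  gr <- suppressWarnings(c(gr_tx, gr_ex))
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read transcript records from GFF3
#'
#' Expects `transcript` features with child `exon` features (via
#' `Parent`), all stranded. Coordinates are converted to the internal
#' 0-based half-open convention.
#'
#' @param path GFF3 file.
#' @return named list of [transcript_record()]s.
#' @export
read_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  if (any(as.character(GenomicRanges::strand(gr)) == "*"))
    stop_domain("unstranded feature in GFF3; strand is required")
  is_tx <- gr$type == "transcript"
  tx <- gr[is_tx]
  ex <- gr[gr$type == "exon"]
  if (length(ex) > 0 && any(lengths(ex$Parent) != 1L))
    stop_domain("every exon needs exactly one Parent")
  parents <- as.character(unlist(ex$Parent))
  orphan <- setdiff(parents, tx$ID)
  if (length(orphan) > 0)
    stop_domain("orphan exon(s) with unknown Parent: ",
                paste(utils::head(orphan, 3), collapse = ", "))
  records <- list()
  for (i in seq_along(tx)) {
    id <- tx$ID[i]
    exi <- ex[parents == id]
    exons <- if (length(exi) > 0)
      cbind(GenomicRanges::start(exi) - 1, GenomicRanges::end(exi))
    else NULL
    records[[id]] <- transcript_record(
      id = id,
      gene_id = tx$gene_id[i] %||% id,
      rna_type = tx$rna_type[i],
      chrom = as.character(GenomicRanges::seqnames(tx[i])),
      start = GenomicRanges::start(tx[i]) - 1,
      end = GenomicRanges::end(tx[i]),
      strand = as.character(GenomicRanges::strand(tx[i])),
      exons = exons,
      is_circular = identical(tx$is_circular_rna[i], "TRUE"))
  }
  records
}

#' Write named sequences to FASTA
#'
#' @param seqs named character vector of sequences (RNA over ACGU or
#'   DNA over ACGT).
#' @param path output file.
#' @param alphabet `"RNA"` or `"DNA"`; validated via Biostrings.
#' @export
write_fasta <- function(seqs, path, alphabet = c("RNA", "DNA")) {
  alphabet <- match.arg(alphabet)
  set <- if (alphabet == "RNA") Biostrings::RNAStringSet(seqs)
  else Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read a FASTA file into a named character vector
#'
#' @param path FASTA file.
#' @param alphabet `"RNA"` or `"DNA"`.
#' @return named character vector.
#' @export
read_fasta <- function(path, alphabet = c("RNA", "DNA")) {
  alphabet <- match.arg(alphabet)
  set <- if (alphabet == "RNA") Biostrings::readRNAStringSet(path)
  else Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(set), names(set))
}

#' Write PFMs in MEME motif format
#'
#' Minimal MEME-motif-format text: version line, alphabet, background
#' frequencies, then one `MOTIF` block per PFM with a
#' `letter-probability matrix` derived from the counts (`nsites` set to
#' each column sum so counts are recoverable).
#'
#' @param pfms list of [pfm()] objects.
#' @param path output file.
#' @param background base frequencies for the header.
#' @export
write_meme <- function(pfms, path, background = rep(0.25, 4)) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               "Background letter frequencies", sprintf(
                 "A %.5f C %.5f G %.5f T %.5f", background[1],
                 background[2], background[3], background[4]), ""), con)
  for (p in pfms) {
    cs <- colSums(p$counts)
    prob <- sweep(p$counts, 2, cs, "/")
    writeLines(sprintf("MOTIF %s", p$tf_name), con)
    writeLines(sprintf(
      "letter-probability matrix: alength= 4 w= %d nsites= %d E= 0",
      ncol(p$counts), round(cs[1L])), con)
    for (j in seq_len(ncol(prob)))
      writeLines(paste(sprintf("%.6f", prob[, j]), collapse = " "), con)
    writeLines("", con)
  }
  invisible(path)
}

#' Read PFMs from MEME motif format
#'
#' @param path MEME-motif-format file (as written by [write_meme()]).
#' @param pseudocount pseudocount for the returned [pfm()] objects.
#' @return named list of [pfm()]s (counts reconstructed as
#'   `probability * nsites`).
#' @export
read_meme <- function(path, pseudocount = 0.25) {
  lines <- readLines(path)
  out <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (grepl("^MOTIF ", lines[i])) {
      name <- sub("^MOTIF +", "", lines[i])
      name <- strsplit(name, " +")[[1L]][1L]
      i <- i + 1L
      hdr <- lines[i]
      w <- as.integer(sub(".*w= *([0-9]+).*", "\\1", hdr))
      nsites <- as.numeric(sub(".*nsites= *([0-9.]+).*", "\\1", hdr))
      mat <- matrix(0, 4, w)
      for (j in seq_len(w)) {
        i <- i + 1L
        mat[, j] <- as.numeric(strsplit(trimws(lines[i]), " +")[[1L]])
      }
      out[[name]] <- pfm(name, round(mat * nsites, 6),
                         pseudocount = pseudocount)
    }
    i <- i + 1L
  }
  out
}

#' Write / read a term-to-gene table
#'
#' TSV with columns `term_id`, `term_name` (optional on read),
#' `gene_id`.
#'
#' @param term_table data frame.
#' @param path file path.
#' @export
write_term_table <- function(term_table, path) {
  utils::write.table(term_table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_term_table
#' @export
read_term_table <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Write / read the planted-truth record as JSON
#'
#' @param truth a `sim_truth` object.
#' @param path file path.
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_truth_json
#' @export
read_truth_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$category_by_lncrna <- lapply(x$category_by_lncrna, unlist)
  x$tf_targets <- lapply(x$tf_targets, unlist)
  for (f in c("coexpr_pairs", "cis_pairs", "motif_sites", "seed_sites"))
    x[[f]] <- as.data.frame(x[[f]], stringsAsFactors = FALSE)
  structure(x, class = "sim_truth")
}
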