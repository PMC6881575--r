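## Synthetic genome layout: transcript records for every probe, with one
## engineered exemplar of each of the six lncRNA positional categories,
## one multi-label exemplar, and a cis-window cassette with coding genes
## at 295 kb (inside the window) and 305 kb (outside). All remaining
## features are isolated by > 300 kb so the planted truth is exhaustive.

## minimum spacing between independent features; exceeds the cis window
## and the divergent-promoter window so isolation implies intergenic
ISOLATION_GAP <- 301000

#' Simulate transcript annotations and their planted truth
#'
#' Lays out coding genes, lncRNAs and circRNAs on the synthetic
#' chromosomes. The first eight lncRNAs and nine coding genes form
#' engineered cassettes: one exemplar per positional category
#' (exon-overlapping, intron-overlapping, natural antisense, intron
#' antisense, bidirectional, intergenic), one two-label crossover
#' exemplar (sense exon overlap with one gene, antisense intronic with
#' another), and one lncRNA flanked by coding genes at gaps of 295,000
#' bp (a cis pair) and 305,000 bp (outside the 300-kb window). All
#' other features are placed with gaps above 301 kb, so they are
#' intergenic and contribute no cis pairs.
#'
#' @param config a [sim_config()] with `n_lncrna >= 8`, `n_mrna >= 9`.
#' @return list with `transcripts` (list of [transcript_record()]s) and
#'   `truth` (category labels per lncRNA and planted cis pairs).
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derive_seeds(config$seed, 4)[2L])
  if (config$n_lncrna < 8L || config$n_mrna < 9L)
    stop_domain("genome cassettes need n_lncrna >= 8 and n_mrna >= 9")
  ids <- probe_ids_for(config)
  truth <- empty_truth()
  records <- list()
  chroms <- sprintf("chr%d", seq_len(config$n_chromosomes))
  cursor <- stats::setNames(rep(0, config$n_chromosomes), chroms)

  add <- function(rec) records[[rec$id]] <<- rec
  gene3 <- function(id, chrom, start, strand, len = 10000) {
    ## coding gene with 3 equal exons separated by 2 introns
    u <- round(len / 5)
    exons <- rbind(c(start, start + u),
                   c(start + 2 * u, start + 3 * u),
                   c(start + 4 * u, start + len))
    transcript_record(id, gene_id = id, rna_type = "mRNA", chrom = chrom,
                      start = start, end = start + len, strand = strand,
                      exons = exons)
  }
  set_cat <- function(lnc_id, labels)
    truth$category_by_lncrna[[lnc_id]] <<- labels
  add_cis <- function(lnc_id, gene_id, d)
    truth$cis_pairs <<- rbind(truth$cis_pairs, data.frame(
      lncrna_id = lnc_id, gene_id = gene_id, distance_bp = d,
      stringsAsFactors = FALSE))

  lnc_ids <- ids$lncrna
  gene_ids <- ids$mrna
  chr1 <- chroms[1L]
  c0 <- 0

  ## 1. exon-overlapping (sense overlap with exon 1)
  add(gene3(gene_ids[1], chr1, c0, "+"))
  add(transcript_record(lnc_ids[1], lnc_ids[1], "lncRNA", chr1,
                        c0 + 1000, c0 + 3000, "+"))
  set_cat(lnc_ids[1], "exon_overlapping")
  add_cis(lnc_ids[1], gene_ids[1], 0)
  c0 <- c0 + 10000 + ISOLATION_GAP

  ## 2. intron-overlapping (sense, inside intron 1 = [2000, 4000))
  add(gene3(gene_ids[2], chr1, c0, "+"))
  add(transcript_record(lnc_ids[2], lnc_ids[2], "lncRNA", chr1,
                        c0 + 2200, c0 + 3800, "+"))
  set_cat(lnc_ids[2], "intron_overlapping")
  add_cis(lnc_ids[2], gene_ids[2], 0)
  c0 <- c0 + 10000 + ISOLATION_GAP

  ## 3. natural antisense (antisense exon overlap)
  add(gene3(gene_ids[3], chr1, c0, "+"))
  add(transcript_record(lnc_ids[3], lnc_ids[3], "lncRNA", chr1,
                        c0 + 1000, c0 + 3000, "-"))
  set_cat(lnc_ids[3], "natural_antisense")
  add_cis(lnc_ids[3], gene_ids[3], 0)
  c0 <- c0 + 10000 + ISOLATION_GAP

  ## 4. intron antisense
  add(gene3(gene_ids[4], chr1, c0, "+"))
  add(transcript_record(lnc_ids[4], lnc_ids[4], "lncRNA", chr1,
                        c0 + 2200, c0 + 3800, "-"))
  set_cat(lnc_ids[4], "intron_antisense")
  add_cis(lnc_ids[4], gene_ids[4], 0)
  c0 <- c0 + 10000 + ISOLATION_GAP

  ## 5. bidirectional: divergent TSSs 500 bp apart, no overlap
  add(transcript_record(lnc_ids[5], lnc_ids[5], "lncRNA", chr1,
                        c0, c0 + 4500, "-"))          # TSS = c0 + 4500
  add(gene3(gene_ids[5], chr1, c0 + 5000, "+"))        # TSS = c0 + 5000
  set_cat(lnc_ids[5], "bidirectional")
  add_cis(lnc_ids[5], gene_ids[5], 500)
  c0 <- c0 + 15000 + ISOLATION_GAP

  ## 6. intergenic exemplar
  add(transcript_record(lnc_ids[6], lnc_ids[6], "lncRNA", chr1,
                        c0, c0 + 2000, "+"))
  set_cat(lnc_ids[6], "intergenic")
  c0 <- c0 + 2000 + ISOLATION_GAP

  ## 7. crossover: sense exon overlap with gene A (- strand) while
  ## antisense inside the long intron of gene B (+ strand)
  gb_start <- c0
  exons_b <- rbind(c(gb_start, gb_start + 1000),
                   c(gb_start + 19000, gb_start + 20000))
  add(transcript_record(gene_ids[6], gene_ids[6], "mRNA", chr1,
                        gb_start, gb_start + 20000, "+",
                        exons = exons_b))
  add(transcript_record(gene_ids[7], gene_ids[7], "mRNA", chr1,
                        gb_start + 4000, gb_start + 9000, "-"))
  add(transcript_record(lnc_ids[7], lnc_ids[7], "lncRNA", chr1,
                        gb_start + 5000, gb_start + 6000, "-"))
  set_cat(lnc_ids[7], c("exon_overlapping", "intron_antisense"))
  add_cis(lnc_ids[7], gene_ids[6], 0)
  add_cis(lnc_ids[7], gene_ids[7], 0)
  c0 <- c0 + 20000 + ISOLATION_GAP

  ## 8. cis-window cassette: gene at 305 kb (excluded), lncRNA, gene at
  ## 295 kb (included)
  add(gene3(gene_ids[8], chr1, c0, "+"))
  lnc8_start <- c0 + 10000 + 305000
  add(transcript_record(lnc_ids[8], lnc_ids[8], "lncRNA", chr1,
                        lnc8_start, lnc8_start + 5000, "+"))
  add(gene3(gene_ids[9], chr1, lnc8_start + 5000 + 295000, "+"))
  set_cat(lnc_ids[8], "intergenic")
  add_cis(lnc_ids[8], gene_ids[9], 295000)
  c0 <- lnc8_start + 5000 + 295000 + 10000 + ISOLATION_GAP
  cursor[chr1] <- c0

  ## remaining features: isolated placement, round-robin over chromosomes
  remaining <- c(
    lapply(gene_ids[-(1:9)], function(id) list(id = id, type = "mRNA")),
    lapply(lnc_ids[-(1:8)], function(id) list(id = id, type = "lncRNA")),
    lapply(ids$circrna, function(id) list(id = id, type = "circRNA")))
  chrom_i <- 1L
  for (f in remaining) {
    len <- switch(f$type,
                  mRNA = sample(5000:20000, 1),
                  lncRNA = sample(1000:5000, 1),
                  circRNA = sample(500:2000, 1))
    strand <- sample(c("+", "-"), 1)
    placed <- FALSE
    for (try in seq_len(config$n_chromosomes)) {
      ch <- chroms[chrom_i]
      chrom_i <- chrom_i %% config$n_chromosomes + 1L
      start <- cursor[[ch]]
      if (start + len + ISOLATION_GAP <= config$genome_length_bp) {
        rec <- if (f$type == "mRNA") {
          gene3(f$id, ch, start, strand, len = len)
        } else if (f$type == "lncRNA") {
          u <- round(len / 4)
          transcript_record(f$id, f$id, "lncRNA", ch, start, start + len,
                            strand,
                            exons = rbind(c(start, start + u),
                                          c(start + 2 * u, start + len)))
        } else {
          transcript_record(f$id, f$id, "circRNA", ch, start,
                            start + len, strand, is_circular = TRUE)
        }
        add(rec)
        if (f$type == "lncRNA") set_cat(f$id, "intergenic")
        cursor[[ch]] <- start + len + ISOLATION_GAP +
          sample(0:50000, 1)
        placed <- TRUE
        break
      }
    }
    if (!placed)
      stop_domain("genome too small to place all requested features; ",
                  "increase genome_length_bp or n_chromosomes")
  }

  list(transcripts = records, truth = truth)
}
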