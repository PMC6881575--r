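## fixtures: a coding gene with exons [0,2000), [4000,6000), [8000,10000)
gene_fix <- function(id = "g1", chrom = "c1", start = 0, strand = "+") {
  transcript_record(id, id, "mRNA", chrom, start, start + 10000, strand,
                    exons = start + rbind(c(0, 2000), c(4000, 6000),
                                          c(8000, 10000)))
}
lnc_fix <- function(id, start, end, strand = "+", chrom = "c1")
  transcript_record(id, id, "lncRNA", chrom, start, end, strand)

test_that("each positional rule fires on its constructed case", {
  g <- gene_fix()
  expect_equal(classify_lncrna(lnc_fix("l", 1000, 3000), list(g))$labels,
               "exon_overlapping")
  expect_equal(classify_lncrna(lnc_fix("l", 2200, 3800), list(g))$labels,
               "intron_overlapping")
  expect_equal(classify_lncrna(lnc_fix("l", 1000, 3000, "-"), list(g))$labels,
               "natural_antisense")
  expect_equal(classify_lncrna(lnc_fix("l", 2200, 3800, "-"), list(g))$labels,
               "intron_antisense")
  ## divergent TSSs 400 bp apart, no overlap
  expect_equal(classify_lncrna(lnc_fix("l", 15000, 19600, "-"),
                               list(gene_fix(start = 20000)))$labels,
               "bidirectional")
  ## convergent orientation at the same distance is not bidirectional
  expect_equal(classify_lncrna(lnc_fix("l", 15000, 19600, "+"),
                               list(gene_fix(start = 20000, strand = "-")))$labels,
               "intergenic")
  expect_equal(classify_lncrna(lnc_fix("l", 50000, 52000), list(g))$labels,
               "intergenic")
  expect_equal(classify_lncrna(lnc_fix("l", 1000, 3000), list())$labels,
               "intergenic")
  expect_equal(classify_lncrna(lnc_fix("l", 1000, 3000, chrom = "c9"),
                               list(g))$labels, "intergenic")
})

test_that("multi-label calls keep the precedence order for primary", {
  ga <- transcript_record("ga", "ga", "mRNA", "c1", 4000, 9000, "-")
  gb <- transcript_record("gb", "gb", "mRNA", "c1", 0, 20000, "+",
                          exons = rbind(c(0, 1000), c(19000, 20000)))
  cl <- classify_lncrna(lnc_fix("l", 5000, 6000, "-"), list(ga, gb))
  expect_setequal(cl$labels, c("exon_overlapping", "intron_antisense"))
  expect_equal(cl$primary, "exon_overlapping")
})

test_that("classification is translation and strand-flip consistent", {
  g <- gene_fix()
  l <- lnc_fix("l", 1000, 3000)
  shift <- function(r, d) {
    r$start <- r$start + d; r$end <- r$end + d; r$exons <- r$exons + d; r
  }
  expect_equal(classify_lncrna(shift(l, 1e6), list(shift(g, 1e6)))$labels,
               classify_lncrna(l, list(g))$labels)
  flip <- function(r) { r$strand <- if (r$strand == "+") "-" else "+"; r }
  ## flipping both preserves sense overlap; flipping one swaps it
  expect_equal(classify_lncrna(flip(l), list(flip(g)))$labels,
               "exon_overlapping")
  expect_equal(classify_lncrna(flip(l), list(g))$labels,
               "natural_antisense")
  li <- lnc_fix("l", 2200, 3800)
  expect_equal(classify_lncrna(flip(li), list(g))$labels,
               "intron_antisense")
})

test_that("classify_all tabulates labels, percentages and Venn parts", {
  g <- gene_fix()
  lncs <- list(lnc_fix("a", 1000, 3000), lnc_fix("b", 2200, 3800),
               lnc_fix("c", 50000, 51000), lnc_fix("d", 60000, 61000))
  res <- classify_all(lncs, list(g))
  expect_equal(unname(res$counts[c("exon_overlapping",
                                   "intron_overlapping", "intergenic")]),
               c(1L, 1L, 2L))
  expect_equal(sum(res$venn), length(lncs))
  expect_equal(unname(res$percent[["intergenic"]]), 50)
  ## intergenic never co-occurs
  for (cl in res$calls)
    if ("intergenic" %in% cl$labels) expect_length(cl$labels, 1L)
})

test_that("random fixtures match the base-set classification oracle", {
  set.seed(23)
  for (rep in 1:6) {
    fx <- random_transcripts(18, 10)
    res <- classify_all(fx$lncs, fx$genes)
    for (l in fx$lncs)
      expect_equal(sort(res$calls[[l$id]]$labels),
                   oracle_classify(l, fx$genes),
                   info = sprintf("rep %d lnc %s", rep, l$id))
  }
})

test_that("cis neighbors respect window, chromosome and ordering", {
  l <- lnc_fix("l", 1000000, 1005000)
  g_in <- transcript_record("gin", "gin", "mRNA", "c1", 1200000, 1210000, "+")
  g_out <- transcript_record("gout", "gout", "mRNA", "c1", 1400000, 1410000, "+")
  g_chr2 <- transcript_record("g2", "g2", "mRNA", "c2", 1000000, 1010000, "+")
  res <- cis_neighbors(l, list(g_out, g_in, g_chr2))
  expect_equal(res$gene_id, "gin")
  expect_equal(res$distance_bp, 195000)
  expect_equal(res$relative_position, "downstream")
  ## upstream naming follows the lncRNA strand
  l_minus <- lnc_fix("l", 1000000, 1005000, "-")
  expect_equal(cis_neighbors(l_minus, list(g_in))$relative_position,
               "upstream")
  ov <- transcript_record("gov", "gov", "mRNA", "c1", 1004000, 1009000, "+")
  both <- cis_neighbors(l, list(g_in, ov))
  expect_equal(both$gene_id, c("gov", "gin"))  # distance then id
  expect_equal(both$distance_bp, c(0, 195000))
})

test_that("cis neighbors agree with the exhaustive scan oracle", {
  set.seed(31)
  for (rep in 1:5) {
    fx <- random_transcripts(10, 30, span = 900000)
    for (l in fx$lncs) {
      got <- cis_neighbors(l, fx$genes)
      want <- oracle_cis(l, fx$genes)
      expect_equal(got$gene_id, want$gene_id)
      expect_equal(got$distance_bp, want$distance_bp)
    }
  }
})

test_that("transcript records validate their invariants", {
  expect_error(transcript_record("x", "x", "mRNA", "c1", 10, 10, "+"),
               "start")
  expect_error(transcript_record("x", "x", "mRNA", "c1", 0, 100, "*"),
               "strand")
  expect_error(transcript_record("x", "x", "mRNA", "c1", 0, 100, "+",
                                 exons = rbind(c(0, 60), c(50, 100))),
               "disjoint")
  expect_error(transcript_record("x", "x", "mRNA", "c1", 10, 100, "+",
                                 exons = rbind(c(0, 60))),
               "contained")
})
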