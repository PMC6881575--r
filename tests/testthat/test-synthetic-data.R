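test_that("configuration invariants are enforced", {
  expect_error(sim_config(n_per_group = 1), "n_per_group")
  expect_error(sim_config(frac_de = 1.5), "frac_de")
  expect_error(sim_config(noise_sd = 0), "noise_sd")
  expect_error(sim_config(n_mrna = -5), "n_mrna")
  expect_s3_class(sim_config(), "sim_config")
})

test_that("a fixed seed fixes every generated byte", {
  cfg <- small_config(seed = 7)
  a <- simulate_study(cfg)
  b <- simulate_study(cfg)
  expect_identical(a$matrix$values, b$matrix$values)
  expect_identical(a$sequences, b$sequences)
  expect_identical(a$promoters, b$promoters)
  expect_identical(lapply(a$pfms, `[[`, "counts"),
                   lapply(b$pfms, `[[`, "counts"))
  expect_identical(a$truth, b$truth)
  c <- simulate_expression(small_config(seed = 8))
  expect_false(identical(a$matrix$values, c$matrix$values))
})

test_that("a null configuration plants nothing", {
  cfg <- small_config(frac_de = 0, n_coexpr_pairs = 0)
  out <- simulate_expression(cfg)
  expect_length(out$truth$de_ids_up, 0)
  expect_length(out$truth$de_ids_down, 0)
  expect_equal(nrow(out$truth$coexpr_pairs), 0)
  expect_true(all(out$matrix$values > 0))
})

test_that("in the zero-noise limit planted probes hit the exact ratio", {
  cfg <- small_config(noise_sd = 1e-9, n_coexpr_pairs = 0)
  out <- simulate_expression(cfg)
  v <- out$matrix$values
  ctrl <- out$matrix$group == "control"
  for (id in out$truth$de_ids_up)
    expect_equal(mean(v[id, !ctrl]) / mean(v[id, ctrl]), 4,
                 tolerance = 1e-6)
  for (id in out$truth$de_ids_down)
    expect_equal(mean(v[id, ctrl]) / mean(v[id, !ctrl]), 4,
                 tolerance = 1e-6)
})

test_that("co-expression plants need enough DE probes", {
  expect_error(simulate_expression(small_config(frac_de = 0,
                                                n_coexpr_pairs = 2)),
               "not enough planted DE")
})

test_that("planted pairs correlate past the gate with the planted sign", {
  out <- simulate_expression(small_config(seed = 3))
  v <- log2(out$matrix$values)
  for (i in seq_len(nrow(out$truth$coexpr_pairs))) {
    pr <- out$truth$coexpr_pairs[i, ]
    r <- stats::cor(v[pr$nc_id, ], v[pr$coding_id, ])
    expect_gt(abs(r), 0.9)
    expect_equal(if (r > 0) "positive" else "negative", pr$sign)
  }
})

test_that("the genome covers all six categories plus the crossover", {
  cfg <- small_config(seed = 5)
  geno <- simulate_genome(cfg)
  truth_cats <- geno$truth$category_by_lncrna
  expect_setequal(
    unique(unlist(truth_cats)),
    c("exon_overlapping", "intron_overlapping", "natural_antisense",
      "intron_antisense", "bidirectional", "intergenic"))
  expect_true(any(lengths(truth_cats) == 2))  # the crossover exemplar
  ## the planted labels are what the classifier reports
  recs <- geno$transcripts
  types <- vapply(recs, `[[`, "", "rna_type")
  lncs <- recs[types == "lncRNA"]
  coding <- recs[types == "mRNA"]
  res <- classify_all(lncs, coding)
  for (id in names(truth_cats))
    expect_setequal(res$calls[[id]]$labels, truth_cats[[id]])
})

test_that("the planted cis window boundary behaves as constructed", {
  cfg <- small_config(seed = 5)
  geno <- simulate_genome(cfg)
  expect_true(all(geno$truth$cis_pairs$distance_bp < 300000))
  expect_true(295000 %in% geno$truth$cis_pairs$distance_bp)
  ## the 295-kb gene is found, the 305-kb gene is not
  recs <- geno$transcripts
  types <- vapply(recs, `[[`, "", "rna_type")
  coding <- recs[types == "mRNA"]
  lnc8 <- recs[["LNC0008"]]
  nb <- cis_neighbors(lnc8, coding)
  expect_equal(nb$gene_id, "MRNA0009")
  expect_equal(nb$distance_bp, 295000)
  ## full truth recovery: planted pairs are exactly what a scan finds
  lncs <- recs[types == "lncRNA"]
  found <- do.call(rbind, lapply(lncs, cis_neighbors, coding = coding))
  expect_setequal(paste(found$lncrna_id, found$gene_id, found$distance_bp),
                  paste(geno$truth$cis_pairs$lncrna_id,
                        geno$truth$cis_pairs$gene_id,
                        geno$truth$cis_pairs$distance_bp))
})

test_that("a too-small genome is a configuration error", {
  cfg <- small_config(genome_length_bp = 2e6, n_chromosomes = 2)
  expect_error(simulate_genome(cfg), "genome too small")
})

test_that("planted seed sites are recovered exactly by the scanner", {
  cfg <- small_config(seed = 9)
  expr <- simulate_expression(cfg)
  seqs <- simulate_sequences(cfg, de_truth = expr$truth)
  all_seqs <- c(seqs$sequences$utr, seqs$sequences$lncrna,
                seqs$sequences$circrna)
  circ_ids <- names(seqs$sequences$circrna)
  found <- seed_site_table(seqs$sequences$mirna, all_seqs,
                           circular_ids = circ_ids)
  tr <- seqs$truth$seed_sites
  expect_equal(nrow(found), nrow(tr))  # scrubbing: truth is exhaustive
  expect_setequal(paste(found$mirna_id, found$target_id, found$offset,
                        found$site_type),
                  paste(tr$mirna_id, tr$target_id, tr$offset,
                        tr$site_type))
  ## the junction plant wraps: it is lost without circular scanning
  j <- tr[tr$offset + 8 > nchar(all_seqs[tr$target_id]), ]
  expect_gte(nrow(j), 1)
  for (i in seq_len(nrow(j))) {
    lin <- find_seed_sites(seqs$sequences$mirna[[j$mirna_id[i]]],
                           all_seqs[[j$target_id[i]]], circular = FALSE)
    expect_false(j$offset[i] %in% lin$offset)
  }
})

test_that("sequence hosts too short for a site are rejected", {
  expect_error(simulate_sequences(small_config(utr_length = 5)),
               "at least 8")
})

test_that("chance 8mer counts on raw background match the closed form", {
  set.seed(77)
  mir <- random_rna(22)
  L <- 2000; n_seq <- 650
  count <- 0
  for (i in seq_len(n_seq)) {
    hits <- find_seed_sites(mir, random_rna(L))
    count <- count + sum(hits$site_type == "8mer")
  }
  lambda <- n_seq * (L - 7) * (1 / 4)^8
  expect_lt(abs(count - lambda), 4 * sqrt(lambda) + 1)
  ## and the much better-powered core-count check: any-type sites are
  ## exactly the 6mer-core matches, expectation (L - 5) / 4^6 per seq
  set.seed(78)
  core_total <- 0
  for (i in 1:200) core_total <- core_total +
      nrow(find_seed_sites(mir, random_rna(L)))
  lambda6 <- 200 * (L - 5) * (1 / 4)^6
  expect_lt(abs(core_total - lambda6), 4 * sqrt(lambda6))
})

test_that("motif plants are recorded faithfully and terms constructed", {
  cfg <- small_config(seed = 13)
  expr <- simulate_expression(cfg)
  mo <- simulate_motifs_and_terms(cfg, de_truth = expr$truth)
  expect_length(mo$pfms, cfg$n_tf)
  expect_equal(length(mo$promoters), cfg$n_lncrna)
  ## every surviving recorded site carries the exact consensus word
  for (i in seq_len(nrow(mo$truth$motif_sites))) {
    s <- mo$truth$motif_sites[i, ]
    cons <- pfm_consensus(mo$pfms[[s$tf]])
    word <- substr(mo$promoters[[s$lncrna_id]], s$offset + 1,
                   s$offset + nchar(cons))
    if (s$strand == "-") {
      comp <- c(A = "T", C = "G", G = "C", T = "A")
      word <- paste(rev(unname(comp[strsplit(word, "")[[1]]])),
                    collapse = "")
    }
    expect_equal(word, cons)
  }
  expect_gte(nrow(mo$truth$motif_sites), cfg$n_tf)  # >= 1 per TF
  ## planted term: enriched in the DE mRNA set by construction
  tt <- mo$term_table
  planted <- tt$gene_id[tt$term_id == mo$truth$enriched_term]
  de_mrna <- intersect(c(expr$truth$de_ids_up, expr$truth$de_ids_down),
                       grep("^MRNA", rownames(expr$matrix$values),
                            value = TRUE))
  expect_gte(length(intersect(planted, de_mrna)), 10)
})

test_that("config files round-trip through YAML and JSON", {
  cfg <- small_config(seed = 21, frac_de = 0.2)
  tmp_y <- tempfile(fileext = ".yaml")
  yaml::write_yaml(unclass(cfg), tmp_y)
  expect_equal(read_sim_config(tmp_y)$frac_de, 0.2)
  tmp_j <- tempfile(fileext = ".json")
  jsonlite::write_json(unclass(cfg), tmp_j, auto_unbox = TRUE, digits = NA)
  cfg_j <- read_sim_config(tmp_j)
  expect_equal(cfg_j$n_mrna, cfg$n_mrna)
  expect_equal(cfg_j$base_freq, cfg$base_freq)
  writeLines("{\"nonsense_field\": 1}", tmp_j)
  expect_error(read_sim_config(tmp_j), "unknown config fields")
})
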