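test_that("log-odds weights follow the pseudocount formula", {
  ## uniform counts against uniform background give zero weights
  p_unif <- pfm("u", matrix(25, 4, 6))
  expect_equal(unname(pfm_log_odds(p_unif)), matrix(0, 4, 6))
  ## one-hot column, vanishing pseudocount: hot base tends to 2 bits
  p_hot <- pfm("h", matrix(c(1, 0, 0, 0), 4, 4), pseudocount = 1e-9)
  w <- pfm_log_odds(p_hot)
  expect_equal(unname(w["A", 1]), 2, tolerance = 1e-3)
  expect_error(pfm("bad", matrix(0, 4, 4)), "positive sum")
  expect_error(pfm("bad", matrix(1, 4, 3)), "width")
})

test_that("the consensus word attains the matrix maximum score", {
  set.seed(2)
  for (i in 1:10) {
    counts <- matrix(stats::rpois(4 * 8, 10) + 1, 4, 8)
    p <- pfm("t", counts)
    w <- pfm_log_odds(p)
    cons <- pfm_consensus(p)
    sc <- scan_promoter(w, cons, both_strands = FALSE)$score
    expect_equal(sc, sum(apply(w, 2, max)), tolerance = 1e-9)
  }
})

test_that("promoter scanning matches a per-position summation oracle", {
  set.seed(6)
  p <- pfm("t", matrix(stats::rpois(4 * 6, 8) + 1, 4, 6))
  w <- pfm_log_odds(p)
  seqc <- paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE),
                collapse = "")
  got <- scan_promoter(w, seqc, both_strands = TRUE)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  chars <- strsplit(seqc, "")[[1]]
  for (i in sample(nrow(got), 80)) {
    off <- got$offset[i]
    word <- chars[(off + 1):(off + 6)]
    if (got$strand[i] == "-")
      word <- rev(unname(comp[word]))
    expect_equal(got$score[i],
                 sum(vapply(seq_along(word),
                            function(j) w[word[j], j], 0)),
                 tolerance = 1e-9)
  }
  expect_equal(nrow(got), 2 * (300 - 6 + 1))
})

test_that("planted consensus scores maximally at its offset and strand", {
  set.seed(8)
  p <- informative_pfm("t", "AACCGGTTACGT")  # not rc-palindromic
  w <- pfm_log_odds(p)
  bg <- paste(sample(c("A", "C", "G", "T"), 400, replace = TRUE),
              collapse = "")
  planted <- bg
  substr(planted, 101, 112) <- "AACCGGTTACGT"
  sc <- scan_promoter(w, planted)
  best <- sc[which.max(sc$score), ]
  expect_equal(best$offset, 100)
  expect_equal(best$strand, "+")
  ## scanning the reverse complement finds the same site on the - strand
  rc <- paste(rev(unname(c(A = "T", C = "G", G = "C", T = "A")[
    strsplit(planted, "")[[1]]])), collapse = "")
  sc_rc <- scan_promoter(w, rc)
  best_rc <- sc_rc[which.max(sc_rc$score), ]
  expect_equal(best_rc$strand, "-")
  expect_equal(best_rc$offset, 400 - 12 - 100)
  expect_equal(sort(sc$score), sort(sc_rc$score), tolerance = 1e-9)
})

test_that("the DP score distribution equals exhaustive enumeration", {
  set.seed(12)
  bases <- c("A", "C", "G", "T")
  for (width in 4:8) {
    p <- pfm("t", matrix(stats::rpois(4 * width, 10) + 1, 4, width))
    w <- pfm_log_odds(p)
    dist <- pwm_score_distribution(w)
    expect_equal(sum(dist$prob), 1, tolerance = 1e-12)
    ## enumerate all 4^width words
    grid <- as.matrix(expand.grid(rep(list(1:4), width)))
    scores <- numeric(nrow(grid))
    for (j in seq_len(width)) scores <- scores + w[grid[, j], j]
    for (thr in sample(dist$score, min(25, length(dist$score)))) {
      enum_tail <- mean(scores >= thr - 1e-9)
      dp_tail <- dist$tail[which(abs(dist$score - thr) < 1e-9)[1]]
      expect_equal(dp_tail, enum_tail, tolerance = 1e-9,
                   info = sprintf("width %d thr %.4f", width, thr))
    }
  }
})

test_that("E-values hit the degenerate bounds", {
  p <- pfm("t", matrix(c(30, 2, 2, 2), 4, 5))
  w <- pfm_log_odds(p)
  maxs <- sum(apply(w, 2, max)); mins <- sum(apply(w, 2, min))
  expect_equal(site_evalue(maxs + 1, w, n_positions_scanned = 1000), 0)
  expect_equal(site_evalue(mins, w, n_positions_scanned = 1000), 1000)
  expect_equal(site_evalue(mins - 5, w, n_positions_scanned = 7), 7)
})

test_that("fully planted promoters give the complete bipartite network", {
  set.seed(14)
  pfms <- list(informative_pfm("TF1", "ACGTACGTACGT"),
               informative_pfm("TF2", "GGGGTTTTCCCC"),
               informative_pfm("TF3", "ACACACGTGTGT"))
  proms <- vapply(1:5, function(i)
    paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE),
          collapse = ""), "")
  names(proms) <- sprintf("lnc%d", 1:5)
  for (i in seq_along(proms))
    for (p in pfms) {
      off <- 20 + 40 * which(vapply(pfms, identical, TRUE, p))
      substr(proms[[i]], off, off + 11) <- pfm_consensus(p)
    }
  net <- build_tf_lncrna_network(pfms, proms, e_max = 0.01)
  expect_equal(unname(net$summary), c(3L, 5L, 15L))
  expect_equal(nrow(net$edges), 15L)
  ## removing one TF removes exactly its edges
  net2 <- build_tf_lncrna_network(pfms[-1], proms, e_max = 0.01)
  expect_equal(net2$edges,
               net$edges[net$edges$tf != "TF1", , drop = FALSE],
               ignore_attr = TRUE)
})

test_that("background scans stay inside the E-value budget", {
  ## no planted motifs: the expected number of positions passing
  ## E < e_max is at most e_max per TF scan by construction; over 60
  ## seeds the total passing-hit count should look Poisson(<= 0.6)
  set.seed(16)
  p <- list(informative_pfm("TF1", "ACGTTGCAGGAT"))
  total <- 0
  for (s in 1:60) {
    proms <- vapply(1:3, function(i)
      paste(sample(c("A", "C", "G", "T"), 250, replace = TRUE),
            collapse = ""), "")
    names(proms) <- sprintf("l%d", 1:3)
    net <- build_tf_lncrna_network(p, proms, e_max = 0.01)
    total <- total + nrow(net$hits)
  }
  expect_lte(total, 6)  # > 5 sigma above the 0.6 budget
})

test_that("TF-target overlap enrichment gives exact tail probabilities", {
  e <- tf_target_enrichment(letters[1:5], letters[1:5], 10)
  expect_equal(e$p, 1 / choose(10, 5), tolerance = 1e-12)
  expect_equal(e$k, 5L)
  e0 <- tf_target_enrichment(letters[1:5], letters[6:10], 10)
  expect_equal(e0$p, 1)
  expect_error(tf_target_enrichment(letters[1:5], letters[1:5], 3),
               "universe")
})

test_that("ternary network is the conjunction of its three conditions", {
  cnc <- structure(data.frame(
    nc_id = c("lnc1", "lnc1", "lnc2"),
    coding_id = c("gA", "gB", "gC"),
    r = c(0.99, 0.95, 0.97), p = c(1e-5, 1e-4, 1e-4),
    q = c(1e-4, 1e-3, 1e-3),
    sign = c("positive", "positive", "negative"),
    stringsAsFactors = FALSE), class = c("cnc_network", "data.frame"))
  tf_edges <- data.frame(tf = c("TFa", "TFa"),
                         lncrna_id = c("lnc1", "lnc2"),
                         stringsAsFactors = FALSE)
  targets <- list(TFa = c("gA", "gC"))
  ## small universe makes the overlap significant for both lncRNAs
  net <- build_ternary_network(cnc, tf_edges, targets, universe_size = 500)
  expect_equal(net$triples,
               data.frame(lncrna_id = c("lnc1", "lnc2"),
                          tf = "TFa", gene_id = c("gA", "gC"),
                          stringsAsFactors = FALSE))
  expect_equal(unname(net$summary), c(2L, 1L, 2L))
  ## deleting the CNC edge deletes the triple
  net2 <- build_ternary_network(cnc[-1, ], tf_edges, targets,
                                universe_size = 500)
  expect_false("gA" %in% net2$triples$gene_id)
  ## relaxing thresholds never removes triples
  net3 <- build_ternary_network(cnc, tf_edges, targets,
                                universe_size = 500, r_min = 0.8,
                                q_max = 0.1)
  expect_true(all(do.call(paste, net$triples) %in%
                    do.call(paste, net3$triples)))
})
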