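test_that("pearson correlation handles exact and degenerate cases", {
  x <- c(1, 2, 3, 4, 5, 6)
  expect_equal(pearson_cor(x, 2 * x), 1)
  expect_equal(pearson_cor(x, -x + 10), -1)
  expect_error(pearson_cor(x, rep(2, 6)), "constant")
  expect_error(pearson_cor(x, x[1:3]), "equal length")
  set.seed(3)
  for (i in 1:30) {
    a <- stats::rnorm(6); b <- stats::rnorm(6)
    manual <- sum((a - mean(a)) * (b - mean(b))) /
      sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
    expect_equal(pearson_cor(a, b), manual, tolerance = 1e-12)
  }
})

test_that("correlation p-value matches the t-transform and cor.test", {
  expect_equal(correlation_pvalue(0, 6), 1)
  expect_equal(correlation_pvalue(1, 6), 0)
  expect_equal(correlation_pvalue(-1, 4), 0)
  ## r = 0.9, n = 6: t = 0.9 * sqrt(4 / 0.19), two-tailed at df 4,
  ## via numeric integration of the t density
  dens <- function(x, df) (1 + x^2 / df)^(-(df + 1) / 2) *
    gamma((df + 1) / 2) / (sqrt(df * pi) * gamma(df / 2))
  tstat <- 0.9 * sqrt(4 / (1 - 0.81))
  p_oracle <- 2 * stats::integrate(dens, tstat, Inf, df = 4)$value
  expect_equal(correlation_pvalue(0.9, 6), p_oracle, tolerance = 1e-8)
  expect_lt(p_oracle, 0.02)
  set.seed(9)
  for (i in 1:20) {
    a <- stats::rnorm(8); b <- stats::rnorm(8)
    ct <- stats::cor.test(a, b)
    expect_equal(correlation_pvalue(unname(ct$estimate), 8), ct$p.value,
                 tolerance = 1e-10)
  }
  expect_error(correlation_pvalue(0.5, 2), "n >= 3")
  expect_error(correlation_pvalue(1.2, 6), "<= 1")
})

## brute-force CNC: per-pair cor.test + double-loop BH, then the gate
oracle_cnc <- function(mat, nc_ids, coding_ids, r_min = 0.9,
                       p_max = 0.01, q_max = 0.01) {
  v <- log2(mat$values)
  grid <- expand.grid(nc = nc_ids, co = coding_ids,
                      stringsAsFactors = FALSE)
  r <- p <- numeric(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    ct <- stats::cor.test(v[grid$nc[i], ], v[grid$co[i], ])
    r[i] <- unname(ct$estimate); p[i] <- ct$p.value
  }
  q <- oracle_bh(p)
  keep <- abs(r) >= r_min & p < p_max & q < q_max
  out <- data.frame(nc_id = grid$nc[keep], coding_id = grid$co[keep],
                    r = r[keep], p = p[keep], q = q[keep],
                    stringsAsFactors = FALSE)
  out[order(out$nc_id, out$coding_id), , drop = FALSE]
}

test_that("build_cnc equals the brute-force double-loop oracle", {
  set.seed(17)
  n_nc <- 20; n_co <- 50
  vals <- matrix(2^(stats::rnorm(70 * 6, mean = 8, sd = 2)), 70, 6)
  ## plant a few strong pairs so the edge set is non-trivial
  for (k in 1:5) vals[k, ] <- vals[k + 20, ] * 2^stats::rnorm(6, sd = 0.1)
  mat <- expression_matrix(
    vals, rep(c("lncRNA", "mRNA"), c(n_nc, n_co)),
    rep(c("control", "case"), each = 3),
    probe_ids = c(sprintf("n%02d", 1:n_nc), sprintf("c%02d", 1:n_co)))
  got <- build_cnc(mat, sprintf("n%02d", 1:n_nc), sprintf("c%02d", 1:n_co))
  want <- oracle_cnc(mat, sprintf("n%02d", 1:n_nc),
                     sprintf("c%02d", 1:n_co))
  expect_equal(got$nc_id, want$nc_id)
  expect_equal(got$coding_id, want$coding_id)
  expect_equal(got$r, want$r, tolerance = 1e-10)
  expect_equal(got$p, want$p, tolerance = 1e-10)
  expect_equal(got$q, want$q, tolerance = 1e-10)
  expect_true(all((got$r > 0) == (got$sign == "positive")))
  expect_gt(nrow(got), 0)
})

test_that("edge counts are monotone in each threshold", {
  set.seed(19)
  vals <- matrix(2^(stats::rnorm(40 * 6, 8, 1.5)), 40, 6)
  for (k in 1:6) vals[k, ] <- vals[k + 20, ] * 2^stats::rnorm(6, sd = 0.05)
  mat <- expression_matrix(vals, rep(c("lncRNA", "mRNA"), each = 20),
                           rep(c("control", "case"), each = 3))
  nc <- rownames(mat$values)[1:20]; co <- rownames(mat$values)[21:40]
  base <- nrow(build_cnc(mat, nc, co, r_min = 0.8, p_max = 0.05,
                         q_max = 0.05))
  expect_lte(nrow(build_cnc(mat, nc, co, r_min = 0.9, p_max = 0.05,
                            q_max = 0.05)), base)
  expect_lte(nrow(build_cnc(mat, nc, co, r_min = 0.8, p_max = 0.01,
                            q_max = 0.05)), base)
  expect_lte(nrow(build_cnc(mat, nc, co, r_min = 0.8, p_max = 0.05,
                            q_max = 0.01)), base)
})

test_that("role transposition preserves r and p for every pair", {
  set.seed(29)
  vals <- matrix(2^(stats::rnorm(20 * 6, 8, 1.5)), 20, 6)
  mat <- expression_matrix(vals, rep(c("lncRNA", "mRNA"), each = 10),
                           rep(c("control", "case"), each = 3))
  a <- rownames(mat$values)[1:10]; b <- rownames(mat$values)[11:20]
  e1 <- build_cnc(mat, a, b, r_min = 0, p_max = 1, q_max = 1)
  e2 <- build_cnc(mat, b, a, r_min = 0, p_max = 1, q_max = 1)
  k1 <- paste(e1$nc_id, e1$coding_id)
  k2 <- paste(e2$coding_id, e2$nc_id)
  expect_setequal(k1, k2)
  m <- match(k1, k2)
  expect_equal(e1$r, e2$r[m], tolerance = 1e-12)
  expect_equal(e1$p, e2$p[m], tolerance = 1e-12)
})

test_that("constant probes are skipped and counted, not fatal", {
  vals <- matrix(2^(stats::rnorm(12 * 6, 8, 1)), 12, 6)
  vals[1, ] <- 256  # constant on both scales
  mat <- expression_matrix(vals, rep(c("lncRNA", "mRNA"), each = 6),
                           rep(c("control", "case"), each = 3))
  nc <- rownames(mat$values)[1:6]; co <- rownames(mat$values)[7:12]
  net <- build_cnc(mat, nc, co)
  expect_equal(attr(net, "n_skipped_constant"), 6L)
  expect_equal(attr(net, "n_pairs_tested"), 30L)
  expect_false(rownames(mat$values)[1] %in% net$nc_id)
})
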