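## Coding-noncoding co-expression (CNC) network: all (noncoding, coding)
## probe pairs scored by Pearson correlation across the pooled samples,
## t-transform p-values, BH FDR over the full pair family, and the joint
## gate |r| >= r_min & p < p_max & q < q_max.

#' Pearson correlation with domain checks
#'
#' Sample product-moment correlation via [stats::cor()], rejecting
#' constant vectors (undefined correlation) and length mismatches.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return correlation in \[-1, 1\].
#' @export
pearson_cor <- function(x, y) {
  if (length(x) != length(y)) stop_domain("'x' and 'y' must have equal length")
  if (length(x) < 3L) stop_domain("need at least 3 paired observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop_domain("correlation undefined for a constant vector")
  stats::cor(x, y)
}

#' Two-tailed p-value for a Pearson correlation
#'
#' Uses the t-transform `t = r * sqrt((n - 2) / (1 - r^2))` with
#' `n - 2` degrees of freedom; `|r| = 1` returns p = 0.
#'
#' @param r correlation in \[-1, 1\].
#' @param n number of paired samples, >= 3.
#' @return two-tailed p-value.
#' @export
correlation_pvalue <- function(r, n) {
  if (any(abs(r) > 1)) stop_domain("|r| must be <= 1")
  if (n < 3) stop_domain("need n >= 3")
  p <- rep(0, length(r))
  ok <- abs(r) < 1
  tstat <- r[ok] * sqrt((n - 2) / (1 - r[ok]^2))
  p[ok] <- 2 * stats::pt(-abs(tstat), df = n - 2)
  p
}

#' Build the coding-noncoding co-expression network
#'
#' Evaluates the Pearson correlation of every (noncoding, coding) probe
#' pair across the pooled samples (both groups), computes t-transform
#' p-values and BH q-values over the full pair family, and keeps pairs
#' passing `|r| >= r_min & p < p_max & q < q_max`. Constant probes are
#' skipped and counted, not fatal.
#'
#' @param mat an [expression_matrix()].
#' @param nc_ids noncoding probe ids (lncRNA and/or circRNA).
#' @param coding_ids coding (mRNA) probe ids.
#' @param r_min,p_max,q_max edge gate (defaults 0.90, 0.01, 0.01).
#' @param samples `"pooled"` (default: both groups) or `"control"` /
#'   `"case"` for per-group networks.
#' @param log2_transform correlate log2 intensities (default `TRUE`,
#'   matching the DE stage's scale).
#' @return object of class `cnc_network`: data frame of edges with
#'   columns `nc_id`, `coding_id`, `r`, `p`, `q`, `sign`
#'   (positive/negative), sorted by (nc_id, coding_id), with attributes
#'   `n_pairs_tested` and `n_skipped_constant`.
#' @export
build_cnc <- function(mat, nc_ids, coding_ids, r_min = 0.90,
                      p_max = 0.01, q_max = 0.01, samples = "pooled",
                      log2_transform = TRUE) {
  stopifnot(inherits(mat, "expr_matrix"))
  check_number(r_min, "r_min", lower = 0, upper = 1)
  missing <- setdiff(c(nc_ids, coding_ids), rownames(mat$values))
  if (length(missing) > 0)
    stop_domain("ids not present in matrix: ",
                paste(utils::head(missing, 5), collapse = ", "))
  keep <- switch(samples,
                 pooled = rep(TRUE, ncol(mat$values)),
                 control = mat$group == "control",
                 case = mat$group == "case",
                 stop_domain("'samples' must be pooled/control/case"))
  v <- mat$values[, keep, drop = FALSE]
  if (log2_transform) v <- log2(v)
  n <- ncol(v)
  if (n < 3L) stop_domain("need at least 3 samples for correlation")
  xnc <- v[nc_ids, , drop = FALSE]
  xco <- v[coding_ids, , drop = FALSE]
  const_nc <- apply(xnc, 1, stats::sd) == 0
  const_co <- apply(xco, 1, stats::sd) == 0
  n_skip <- sum(const_nc) * length(coding_ids) +
    sum(const_co) * length(nc_ids) -
    sum(const_nc) * sum(const_co)
  xnc <- xnc[!const_nc, , drop = FALSE]
  xco <- xco[!const_co, , drop = FALSE]
  if (nrow(xnc) == 0L || nrow(xco) == 0L) {
    edges <- data.frame(nc_id = character(0), coding_id = character(0),
                        r = numeric(0), p = numeric(0), q = numeric(0),
                        sign = character(0), stringsAsFactors = FALSE)
    return(structure(edges, n_pairs_tested = 0L,
                     n_skipped_constant = n_skip,
                     thresholds = c(r_min = r_min, p_max = p_max,
                                    q_max = q_max),
                     class = c("cnc_network", "data.frame")))
  }
  rmat <- stats::cor(t(xnc), t(xco))
  ## numerical safety: clamp tiny excursions past +/-1
  rmat[rmat > 1] <- 1; rmat[rmat < -1] <- -1
  pairs <- expand.grid(nc_id = rownames(xnc), coding_id = rownames(xco),
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  rvec <- as.vector(rmat)
  pvec <- correlation_pvalue(rvec, n)
  qvec <- bh_adjust(pvec)
  pass <- abs(rvec) >= r_min & pvec < p_max & qvec < q_max
  edges <- data.frame(
    nc_id = pairs$nc_id[pass],
    coding_id = pairs$coding_id[pass],
    r = rvec[pass], p = pvec[pass], q = qvec[pass],
    sign = ifelse(rvec[pass] > 0, "positive", "negative"),
    stringsAsFactors = FALSE)
  edges <- edges[order(edges$nc_id, edges$coding_id), , drop = FALSE]
  rownames(edges) <- NULL
  structure(edges,
            n_pairs_tested = length(rvec),
            n_skipped_constant = n_skip,
            thresholds = c(r_min = r_min, p_max = p_max, q_max = q_max),
            class = c("cnc_network", "data.frame"))
}

#' @export
print.cnc_network <- function(x, ...) {
  th <- attr(x, "thresholds")
  cat(sprintf(
    "CNC network: %d edges from %d pairs (|r| >= %g, p < %g, q < %g; %d constant pairs skipped)\n",
    nrow(x), attr(x, "n_pairs_tested"), th["r_min"], th["p_max"],
    th["q_max"], attr(x, "n_skipped_constant")))
  cat(sprintf("  %d positive, %d negative\n",
              sum(x$sign == "positive"), sum(x$sign == "negative")))
  invisible(x)
}
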