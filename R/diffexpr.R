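## Differential expression: fold change on linear-scale group means,
## two-tailed pooled-variance Student t-test, Benjamini-Hochberg FDR, and
## the joint significance filter fc >= fc_min & p < p_max & q < q_max,
## partitioned into up/down sets within each RNA class.

#' Fold change between two groups of positive intensities
#'
#' Computes the ratio of group means on the linear scale and folds it to
#' a magnitude >= 1 with a direction: `up` when the case mean exceeds the
#' control mean, `down` when it is lower, `none` when equal.
#'
#' @param control_values,case_values positive numeric vectors.
#' @return list with elements `fc` (>= 1) and `direction`.
#' @examples
#' fold_change(c(2, 2, 2), c(4, 4, 4))  # fc 2, up
#' @export
fold_change <- function(control_values, case_values) {
  if (length(control_values) == 0L || length(case_values) == 0L)
    stop_domain("both groups must be non-empty")
  if (any(control_values <= 0) || any(case_values <= 0))
    stop_domain("intensities must be positive")
  r <- mean(case_values) / mean(control_values)
  list(fc = max(r, 1 / r),
       direction = if (r > 1) "up" else if (r < 1) "down" else "none")
}

#' Two-tailed pooled-variance Student t-test p-value
#'
#' Equal-variance two-sample t statistic with `n1 + n2 - 2` degrees of
#' freedom. Identical groups with zero pooled variance return p = 1 by
#' convention; zero pooled variance with unequal means is rejected as a
#' degenerate input.
#'
#' @param control_values,case_values numeric vectors, each of length >= 2.
#' @param welch if `TRUE` use the Welch (unequal-variance) form instead.
#' @return two-tailed p-value in \[0, 1\].
#' @export
student_t_pvalue <- function(control_values, case_values, welch = FALSE) {
  n1 <- length(control_values); n2 <- length(case_values)
  if (n1 < 2L || n2 < 2L)
    stop_domain("each group needs at least 2 values")
  m1 <- mean(control_values); m2 <- mean(case_values)
  v1 <- stats::var(control_values); v2 <- stats::var(case_values)
  if (v1 == 0 && v2 == 0) {
    if (m1 == m2) return(1)
    stop_domain("zero variance in both groups with unequal means")
  }
  if (welch) {
    se2 <- v1 / n1 + v2 / n2
    tstat <- (m2 - m1) / sqrt(se2)
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  } else {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    tstat <- (m2 - m1) / sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  }
  2 * stats::pt(-abs(tstat), df = df)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Thin validating wrapper over [stats::p.adjust()] with `method = "BH"`:
#' q_(i) = min over j >= i of p_(j) * m / j, capped at 1, returned in the
#' input order.
#'
#' @param pvalues numeric vector of p-values in \[0, 1\].
#' @return adjusted q-values, same length and order.
#' @export
bh_adjust <- function(pvalues) {
  if (length(pvalues) == 0L) return(numeric(0))
  if (anyNA(pvalues) || any(pvalues < 0) || any(pvalues > 1))
    stop_domain("p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

## Vectorized per-row pooled t-test on a probes x samples matrix.
## Returns p-values; rows with zero pooled variance get p = 1 when the
## group means are equal and p = 0 (the infinite-t limit) otherwise,
## with the count of such degenerate rows attached as an attribute.
#' @noRd
row_t_pvalues <- function(x, is_case, welch = FALSE) {
  x1 <- x[, !is_case, drop = FALSE]
  x2 <- x[, is_case, drop = FALSE]
  n1 <- ncol(x1); n2 <- ncol(x2)
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  v1 <- rowSums((x1 - m1)^2) / (n1 - 1)
  v2 <- rowSums((x2 - m2)^2) / (n2 - 1)
  if (welch) {
    se2 <- v1 / n1 + v2 / n2
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
    tstat <- (m2 - m1) / sqrt(se2)
  } else {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    df <- n1 + n2 - 2
    tstat <- (m2 - m1) / sqrt(sp2 * (1 / n1 + 1 / n2))
  }
  p <- 2 * stats::pt(-abs(tstat), df = df)
  degen <- v1 == 0 & v2 == 0
  if (any(degen)) {
    p[degen & m1 == m2] <- 1
    p[degen & m1 != m2] <- 0
  }
  attr(p, "n_degenerate") <- sum(degen & m1 != m2)
  p
}

#' Run the differential-expression stage
#'
#' For every probe: fold change of linear-scale group means, two-tailed
#' Student t-test on log2 intensities, BH-adjusted q-value, and the joint
#' significance rule `fc >= fc_min & p < p_max & q < q_max`. By default
#' the BH adjustment is applied separately within each RNA class (the
#' classes are assayed on separate array designs); set `stratify = FALSE`
#' to adjust over the pooled probe list.
#'
#' @param mat an [expression_matrix()] object.
#' @param fc_min,p_max,q_max thresholds of the joint rule (defaults 2.0,
#'   0.05, 0.05).
#' @param welch use the Welch t-test instead of pooled-variance Student.
#' @param stratify adjust FDR within each RNA class separately.
#' @param log2_input set to `TRUE` if `mat` already holds log2 values;
#'   they are then exponentiated for the fold change and used directly
#'   for the t-test.
#' @return an object of class `de_result`: a data frame with columns
#'   `probe_id`, `rna_type`, `fc`, `direction`, `p`, `q`, `passes`, with
#'   attributes `partitions` (per-class up/down probe id lists),
#'   `thresholds`, and `n_degenerate` (probes with zero variance in both
#'   groups but unequal means, reported with p = 0 rather than aborting).
#' @export
run_de <- function(mat, fc_min = 2.0, p_max = 0.05, q_max = 0.05,
                   welch = FALSE, stratify = TRUE, log2_input = FALSE) {
  stopifnot(inherits(mat, "expr_matrix"))
  check_number(fc_min, "fc_min", lower = 1)
  check_number(p_max, "p_max", lower = 0, upper = 1)
  check_number(q_max, "q_max", lower = 0, upper = 1)
  vals <- mat$values
  logv <- if (log2_input) vals else log2(vals)
  linv <- if (log2_input) 2^vals else vals
  is_case <- mat$group == "case"
  m_ctrl <- rowMeans(linv[, !is_case, drop = FALSE])
  m_case <- rowMeans(linv[, is_case, drop = FALSE])
  ratio <- m_case / m_ctrl
  fc <- pmax(ratio, 1 / ratio)
  direction <- ifelse(ratio > 1, "up", ifelse(ratio < 1, "down", "none"))
  p <- row_t_pvalues(logv, is_case, welch = welch)
  n_degen <- attr(p, "n_degenerate")
  q <- rep(NA_real_, length(p))
  if (stratify) {
    for (cls in unique(mat$rna_type)) {
      i <- mat$rna_type == cls
      q[i] <- bh_adjust(p[i])
    }
  } else {
    q <- bh_adjust(as.numeric(p))
  }
  passes <- fc >= fc_min & p < p_max & q < q_max
  res <- data.frame(
    probe_id = rownames(vals),
    rna_type = unname(mat$rna_type),
    fc = unname(fc),
    direction = unname(direction),
    p = as.numeric(p),
    q = q,
    passes = unname(passes),
    stringsAsFactors = FALSE)
  partitions <- lapply(split(res, res$rna_type), function(d) {
    list(up = d$probe_id[d$passes & d$direction == "up"],
         down = d$probe_id[d$passes & d$direction == "down"])
  })
  structure(res,
            partitions = partitions,
            thresholds = c(fc_min = fc_min, p_max = p_max, q_max = q_max),
            n_degenerate = n_degen,
            class = c("de_result", "data.frame"))
}

#' Up/down probe-id partitions of a DE run
#' @param de a `de_result` object from [run_de()].
#' @return named list: per RNA class, lists `up` and `down` of probe ids.
#' @export
de_partitions <- function(de) attr(de, "partitions")

#' @export
print.de_result <- function(x, ...) {
  th <- attr(x, "thresholds")
  cat(sprintf(
    "differential expression: %d probes, rule fc >= %g & p < %g & q < %g\n",
    nrow(x), th["fc_min"], th["p_max"], th["q_max"]))
  for (cls in names(attr(x, "partitions"))) {
    p <- attr(x, "partitions")[[cls]]
    cat(sprintf("  %-7s %4d up, %4d down\n", cls,
                length(p$up), length(p$down)))
  }
  invisible(x)
}
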