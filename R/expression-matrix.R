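## ExpressionMatrix container: probes x samples linear-scale intensities
## with an RNA class per probe and a two-level group label per sample.

#' Construct an expression matrix object
#'
#' Container for normalized, linear-scale microarray intensities for a
#' two-group comparison. Rows are probes (mRNA, lncRNA or circRNA), and
#' columns are samples labelled `control` or `case`.
#'
#' @param values numeric matrix, probes x samples, all values > 0, no
#'   missing entries. Row names are taken as probe ids if `probe_ids` is
#'   not given.
#' @param rna_type character vector, one of `"mRNA"`, `"lncRNA"`,
#'   `"circRNA"` per probe.
#' @param group character vector, one of `"control"`, `"case"` per
#'   sample; each group needs at least two samples.
#' @param probe_ids,sample_ids optional explicit identifiers.
#' @return an object of class `expr_matrix`: a list with elements
#'   `values`, `rna_type`, `group`.
#' @export
expression_matrix <- function(values, rna_type, group,
                              probe_ids = rownames(values),
                              sample_ids = colnames(values)) {
  if (!is.matrix(values) || !is.numeric(values))
    stop_domain("'values' must be a numeric matrix")
  if (is.null(probe_ids)) probe_ids <- paste0("probe_", seq_len(nrow(values)))
  if (is.null(sample_ids)) sample_ids <- paste0("sample_", seq_len(ncol(values)))
  probe_ids <- as.character(probe_ids)
  sample_ids <- as.character(sample_ids)
  if (anyDuplicated(probe_ids))
    stop_domain("probe ids must be unique")
  if (length(probe_ids) != nrow(values) || length(sample_ids) != ncol(values))
    stop_domain("id lengths do not match matrix dimensions")
  if (anyNA(values))
    stop_domain("expression values must not contain missing entries")
  if (any(values <= 0))
    stop_domain("expression values must all be positive (linear scale)")
  rna_type <- as.character(rna_type)
  if (length(rna_type) != nrow(values) ||
      !all(rna_type %in% c("mRNA", "lncRNA", "circRNA")))
    stop_domain("'rna_type' must be mRNA/lncRNA/circRNA, one per probe")
  group <- as.character(group)
  if (length(group) != ncol(values) ||
      !all(group %in% c("control", "case")))
    stop_domain("'group' must be control/case, one per sample")
  if (sum(group == "control") < 2L || sum(group == "case") < 2L)
    stop_domain("each group needs at least 2 samples")
  dimnames(values) <- list(probe_ids, sample_ids)
  structure(
    list(values = values,
         rna_type = stats::setNames(rna_type, probe_ids),
         group = stats::setNames(group, sample_ids)),
    class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  tab <- table(x$rna_type)
  cat(sprintf(
    "expression matrix: %d probes x %d samples (%d control, %d case)\n",
    nrow(x$values), ncol(x$values),
    sum(x$group == "control"), sum(x$group == "case")))
  cat("probes by class:",
      paste(sprintf("%s=%d", names(tab), as.integer(tab)), collapse = ", "),
      "\n")
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)
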