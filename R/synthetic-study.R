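## One-call generator for the full synthetic study.

#' Simulate the complete synthetic study
#'
#' Runs the expression, genome, sequence and motif/term generators
#' under one configuration (each on its own sub-seed derived from
#' `config$seed`) and merges their planted truths. This is the standard
#' fixture: every downstream stage of the pipeline can be checked
#' against the returned truth.
#'
#' @param config a [sim_config()].
#' @return object of class `sim_study`: list with `config`, `matrix`
#'   (an [expression_matrix()]), `transcripts`, `sequences`, `pfms`,
#'   `promoters`, `tf_targets`, `term_table`, and `truth`.
#' @export
simulate_study <- function(config = sim_config()) {
  expr <- simulate_expression(config)
  geno <- simulate_genome(config)
  seqs <- simulate_sequences(config, de_truth = expr$truth)
  moti <- simulate_motifs_and_terms(config, de_truth = expr$truth)
  truth <- expr$truth
  truth$category_by_lncrna <- geno$truth$category_by_lncrna
  truth$cis_pairs <- geno$truth$cis_pairs
  truth$seed_sites <- seqs$truth$seed_sites
  truth$motif_sites <- moti$truth$motif_sites
  truth$tf_targets <- moti$truth$tf_targets
  truth$enriched_term <- moti$truth$enriched_term
  structure(
    list(config = config,
         matrix = expr$matrix,
         transcripts = geno$transcripts,
         sequences = seqs$sequences,
         pfms = moti$pfms,
         promoters = moti$promoters,
         tf_targets = moti$tf_targets,
         term_table = moti$term_table,
         truth = truth),
    class = "sim_study")
}

#' @export
print.sim_study <- function(x, ...) {
  cat("synthetic study fixture\n")
  print(x$config)
  print(x$matrix)
  print(x$truth)
  invisible(x)
}
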