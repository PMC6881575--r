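## End-to-end pipeline driver: DE filter -> lncRNA classification ->
## cis candidates -> CNC network -> TF-lncRNA networks (up/down) ->
## ternary trans-regulation network -> ceRNA network -> term
## enrichment, with every table and network written to disk and a run
## report of the headline counts.

#' Pipeline configuration
#'
#' Collects every stage threshold with the defaults of the analysis the
#' package implements (fold change >= 2.0, p < 0.05, FDR < 0.05 for DE;
#' |PCC| >= 0.90, p < 0.01, FDR < 0.01 for CNC edges; 300-kb cis
#' window; motif E < 0.01; |PCC| >= 0.9, FDR <= 0.05 for ternary
#' triples; enrichment p < 0.05 with the top-10 display rule), plus the
#' simulation configuration used in simulate-first mode.
#'
#' @param out_dir output directory (created if missing).
#' @param sim a [sim_config()] for simulate-first runs.
#' @param fc_min,de_p,de_q DE thresholds.
#' @param cnc_r,cnc_p,cnc_q CNC edge gate.
#' @param cis_window_bp cis window (bp).
#' @param bidir_window_bp divergent-promoter window (bp).
#' @param motif_e_max motif E-value gate.
#' @param ternary_r,ternary_q co-expression gate for ternary triples.
#' @param enrich_p_max,enrich_top enrichment display rule.
#' @param welch,pooled_bh,log2_input DE flags (see [run_de()]).
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, sim = sim_config(),
                            fc_min = 2.0, de_p = 0.05, de_q = 0.05,
                            cnc_r = 0.90, cnc_p = 0.01, cnc_q = 0.01,
                            cis_window_bp = 300000,
                            bidir_window_bp = 1000,
                            motif_e_max = 0.01,
                            ternary_r = 0.9, ternary_q = 0.05,
                            enrich_p_max = 0.05, enrich_top = 10,
                            welch = FALSE, pooled_bh = FALSE,
                            log2_input = FALSE) {
  stopifnot(inherits(sim, "sim_config"))
  structure(as.list(environment()), class = "pipeline_config")
}

#' @noRd
write_df <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

#' Run the full analysis pipeline
#'
#' In simulate-first mode (the default) the synthetic study is
#' generated from `config$sim`, all inputs are written to
#' `config$out_dir/inputs`, every stage is executed at the configured
#' thresholds, and all result tables/networks plus a run report are
#' written to `config$out_dir`. Identical config and seed produce
#' byte-identical outputs. A stage failure aborts the run with the
#' stage name and removes the partially written outputs.
#'
#' @param config a [pipeline_config()].
#' @param study optional pre-built [simulate_study()] bundle (bypasses
#'   simulation, e.g. for re-running stages on saved inputs).
#' @return object of class `pipeline_result`: list of all stage
#'   results plus the planted truth.
#' @export
run_pipeline <- function(config, study = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  created <- !dir.exists(out)
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out, "inputs"), showWarnings = FALSE)
  stage <- "simulate"
  res <- tryCatch({
    if (is.null(study)) study <- simulate_study(config$sim)

    ## persist the inputs
    write_expression_tsv(study$matrix, file.path(out, "inputs", "expression.tsv"))
    write_gff3(study$transcripts, file.path(out, "inputs", "annotation.gff3"))
    write_fasta(study$sequences$utr, file.path(out, "inputs", "utr.fa"), "RNA")
    write_fasta(study$sequences$lncrna, file.path(out, "inputs", "lncrna.fa"), "RNA")
    if (length(study$sequences$circrna) > 0)
      write_fasta(study$sequences$circrna, file.path(out, "inputs", "circrna.fa"), "RNA")
    write_fasta(study$sequences$mirna, file.path(out, "inputs", "mirna.fa"), "RNA")
    write_fasta(study$promoters, file.path(out, "inputs", "promoters.fa"), "DNA")
    write_meme(study$pfms, file.path(out, "inputs", "motifs.meme"))
    write_term_table(study$term_table, file.path(out, "inputs", "terms.tsv"))
    write_truth_json(study$truth, file.path(out, "inputs", "truth.json"))

    stage <- "differential expression"
    de <- run_de(study$matrix, fc_min = config$fc_min,
                 p_max = config$de_p, q_max = config$de_q,
                 welch = config$welch, stratify = !config$pooled_bh,
                 log2_input = config$log2_input)
    parts <- de_partitions(de)
    de_lnc_up <- parts$lncRNA$up %||% character(0)
    de_lnc_down <- parts$lncRNA$down %||% character(0)
    de_lnc <- c(de_lnc_up, de_lnc_down)
    de_circ <- c(parts$circRNA$up %||% character(0),
                 parts$circRNA$down %||% character(0))
    de_mrna_up <- parts$mRNA$up %||% character(0)
    de_mrna_down <- parts$mRNA$down %||% character(0)
    de_mrna <- c(de_mrna_up, de_mrna_down)
    write_df(as.data.frame(de), file.path(out, "de_results.tsv"))

    stage <- "lncRNA classification"
    recs <- study$transcripts
    rec_types <- vapply(recs, `[[`, "", "rna_type")
    lncs <- recs[rec_types == "lncRNA"]
    coding <- recs[rec_types == "mRNA"]
    classification <- classify_all(lncs, coding,
                                   bidir_window_bp = config$bidir_window_bp)
    calls_df <- do.call(rbind, lapply(classification$calls, function(cl)
      data.frame(lncrna_id = cl$lncrna_id,
                 labels = paste(cl$labels, collapse = "+"),
                 primary = cl$primary, stringsAsFactors = FALSE)))
    write_df(calls_df, file.path(out, "lncrna_categories.tsv"))
    write_df(data.frame(label_set = names(classification$venn),
                        n = classification$venn),
             file.path(out, "lncrna_venn.tsv"))

    stage <- "cis candidates"
    cis <- do.call(rbind, c(
      list(data.frame(lncrna_id = character(0), gene_id = character(0),
                      distance_bp = numeric(0),
                      relative_position = character(0),
                      stringsAsFactors = FALSE)),
      lapply(lncs[names(lncs) %in% de_lnc], cis_neighbors,
             coding = coding, window_bp = config$cis_window_bp)))
    write_df(cis, file.path(out, "cis_pairs.tsv"))

    stage <- "CNC network"
    cnc <- build_cnc(study$matrix, nc_ids = c(de_lnc, de_circ),
                     coding_ids = de_mrna, r_min = config$cnc_r,
                     p_max = config$cnc_p, q_max = config$cnc_q)
    write_df(as.data.frame(cnc), file.path(out, "cnc_edges.tsv"))
    export_network(cnc, file.path(out, "cnc_edges.sif"), "SIF")

    stage <- "TF-lncRNA networks"
    tf_up <- build_tf_lncrna_network(
      study$pfms, study$promoters[names(study$promoters) %in% de_lnc_up],
      e_max = config$motif_e_max)
    tf_down <- build_tf_lncrna_network(
      study$pfms, study$promoters[names(study$promoters) %in% de_lnc_down],
      e_max = config$motif_e_max)
    write_df(tf_up$edges, file.path(out, "tf_lncrna_up.tsv"))
    write_df(tf_down$edges, file.path(out, "tf_lncrna_down.tsv"))

    stage <- "ternary network"
    tf_edges <- rbind(tf_up$edges, tf_down$edges)
    ternary <- build_ternary_network(
      cnc, tf_edges, study$tf_targets,
      universe_size = length(study$matrix$rna_type[
        study$matrix$rna_type == "mRNA"]),
      r_min = config$ternary_r, q_max = config$ternary_q)
    write_df(ternary$triples, file.path(out, "ternary_triples.tsv"))

    stage <- "ceRNA network"
    targets <- c(study$sequences$lncrna[names(study$sequences$lncrna)
                                        %in% de_lnc],
                 study$sequences$circrna[names(study$sequences$circrna)
                                         %in% de_circ],
                 study$sequences$utr[names(study$sequences$utr)
                                     %in% de_mrna])
    sites <- seed_site_table(study$sequences$mirna, targets,
                             circular_ids = names(study$sequences$circrna))
    cerna <- build_cerna(c(de_lnc, de_circ), de_mrna, sites)
    write_df(sites, file.path(out, "seed_sites.tsv"))
    write_df(cerna$triples, file.path(out, "cerna_triples.tsv"))
    export_network(cerna, file.path(out, "cerna_edges.sif"), "SIF")

    stage <- "term enrichment"
    universe <- names(study$matrix$rna_type)[
      study$matrix$rna_type == "mRNA"]
    enr_up <- enrich_terms(de_mrna_up, study$term_table, universe,
                           p_max = config$enrich_p_max,
                           top = config$enrich_top)
    enr_down <- enrich_terms(de_mrna_down, study$term_table, universe,
                             p_max = config$enrich_p_max,
                             top = config$enrich_top)
    write_df(as.data.frame(enr_up), file.path(out, "enrichment_up.tsv"))
    write_df(as.data.frame(enr_down), file.path(out, "enrichment_down.tsv"))
    pg <- pathway_gene_network(enr_up, de_mrna_up, study$term_table)
    write_df(pg, file.path(out, "pathway_gene_edges.tsv"))

    stage <- "report"
    report <- c(
      "pipeline run report",
      sprintf("thresholds: fc >= %g, de p < %g, de q < %g; CNC |r| >= %g, p < %g, q < %g; cis window %d bp; motif E < %g; ternary |r| >= %g, q <= %g; enrichment p < %g (top %d)",
              config$fc_min, config$de_p, config$de_q, config$cnc_r,
              config$cnc_p, config$cnc_q, config$cis_window_bp,
              config$motif_e_max, config$ternary_r, config$ternary_q,
              config$enrich_p_max, config$enrich_top),
      sprintf("differentially expressed: %d lncRNAs (%d up, %d down), %d mRNAs (%d up, %d down), %d circRNAs",
              length(de_lnc), length(de_lnc_up), length(de_lnc_down),
              length(de_mrna), length(de_mrna_up), length(de_mrna_down),
              length(de_circ)),
      sprintf("CNC network: %d edges from %d pairs (%d constant pairs skipped)",
              nrow(cnc), attr(cnc, "n_pairs_tested"),
              attr(cnc, "n_skipped_constant")),
      sprintf("up-regulated lncRNAs-TFs network: %d TFs and %d correlated lncRNAs connected by %d edges",
              tf_up$summary["n_tfs"], tf_up$summary["n_lncrnas"],
              tf_up$summary["n_edges"]),
      sprintf("down-regulated lncRNAs-TFs network: %d TFs and %d correlated lncRNAs connected by %d edges",
              tf_down$summary["n_tfs"], tf_down$summary["n_lncrnas"],
              tf_down$summary["n_edges"]),
      sprintf("lncRNA-TF-gene network: %d lncRNAs, %d TFs, %d correlated genes",
              ternary$summary["n_lncrnas"], ternary$summary["n_tfs"],
              ternary$summary["n_genes"]),
      sprintf("ceRNA network: %d triples", nrow(cerna$triples)),
      sprintf("cis pairs within window: %d", nrow(cis)),
      sprintf("enriched terms displayed: %d up, %d down",
              nrow(enr_up), nrow(enr_down)))
    writeLines(report, file.path(out, "report.txt"))

    structure(
      list(study = study, de = de, classification = classification,
           cis = cis, cnc = cnc, tf_up = tf_up, tf_down = tf_down,
           ternary = ternary, cerna = cerna, seed_sites = sites,
           enrichment_up = enr_up, enrichment_down = enr_down,
           pathway_gene = pg, report = report, truth = study$truth),
      class = "pipeline_result")
  }, error = function(e) {
    unlink(out, recursive = TRUE)
    stop_domain(sprintf("pipeline stage '%s' failed: %s", stage,
                        conditionMessage(e)))
  })
  res
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(paste(x$report, collapse = "\n"), "\n")
  invisible(x)
}
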