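## Simulation configuration and planted-truth containers.

#' Simulation configuration
#'
#' Parameters of the synthetic study: a two-group (control vs case)
#' microarray design over mRNA, lncRNA and circRNA probes with planted
#' differential expression, co-expressed noncoding/coding pairs,
#' genomic configurations for all six lncRNA positional categories,
#' miRNA seed sites, promoter motifs, and one over-represented term.
#'
#' The defaults are the study conditions the generator emulates: a
#' 3-vs-3 design, log-normal intensity noise (`noise_sd` in log2 units),
#' planted fold changes of 2^2 = 4 (`planted_log2fc = 2`, comfortably
#' past the fold-change >= 2 gate), and a tenth of probes differentially
#' expressed.
#'
#' @param seed integer RNG seed; fixes every generated byte.
#' @param n_per_group samples per group (default 3).
#' @param n_mrna,n_lncrna,n_circrna probe counts (defaults 2000, 300,
#'   100). The genome generator needs `n_lncrna >= 8` and
#'   `n_mrna >= 9` to place one exemplar of every positional category.
#' @param frac_de fraction of probes per class planted as differentially
#'   expressed (default 0.1), split evenly up/down.
#' @param planted_log2fc planted case-group effect in log2 units
#'   (default 2.0).
#' @param noise_sd within-group SD in log2 units (default 0.25).
#' @param n_coexpr_pairs planted noncoding-coding co-expressed pairs
#'   (default 20); pair members are drawn from the planted DE probes.
#' @param coexpr_target_r planted within-group noise correlation of
#'   co-expressed pairs (default 0.97; must exceed the 0.90 network
#'   gate with margin because six samples make the sample correlation
#'   noisy). The pair members share this fraction of their noise
#'   variance through a per-sample latent factor, so their within-group
#'   SD stays at `noise_sd`; the pooled correlation is reinforced
#'   further by the sign-aligned group shift.
#' @param n_mirna miRNA count (default 8).
#' @param n_tf transcription-factor PFM count (default 6).
#' @param genome_length_bp length of each synthetic chromosome
#'   (default 2.5e8).
#' @param n_chromosomes number of chromosomes (default 5).
#' @param utr_length,lnc_seq_length,circ_seq_length,mirna_length
#'   generated sequence lengths in nt (defaults 300, 500, 300, 22).
#' @param promoter_up,promoter_down promoter window around the TSS in
#'   bp (defaults 2000 and 200; promoter sequences have length
#'   `promoter_up + promoter_down`).
#' @param n_terms,term_size term table geometry (defaults 30 terms of
#'   20 genes); the planted term gets `enriched_term_de` of its genes
#'   (default 15) from the planted DE mRNA set.
#' @param base_freq background base composition (default uniform).
#' @param scrub_background remove chance miRNA seed-core matches from
#'   generated sequences so the planted seed-site truth is exhaustive
#'   (default `TRUE`).
#' @return object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_per_group = 3L,
                       n_mrna = 2000L,
                       n_lncrna = 300L,
                       n_circrna = 100L,
                       frac_de = 0.1,
                       planted_log2fc = 2.0,
                       noise_sd = 0.25,
                       n_coexpr_pairs = 20L,
                       coexpr_target_r = 0.97,
                       n_mirna = 8L,
                       n_tf = 6L,
                       genome_length_bp = 2.5e8,
                       n_chromosomes = 5L,
                       utr_length = 300L,
                       lnc_seq_length = 500L,
                       circ_seq_length = 300L,
                       mirna_length = 22L,
                       promoter_up = 2000L,
                       promoter_down = 200L,
                       n_terms = 30L,
                       term_size = 20L,
                       enriched_term_de = 15L,
                       base_freq = rep(0.25, 4),
                       scrub_background = TRUE) {
  cfg <- as.list(environment())
  check_number(seed, "seed", integer = TRUE)
  check_number(n_per_group, "n_per_group", lower = 2, integer = TRUE)
  for (count_field in c("n_mrna", "n_lncrna", "n_circrna",
                        "n_coexpr_pairs", "n_mirna", "n_tf",
                        "n_chromosomes", "utr_length", "lnc_seq_length",
                        "circ_seq_length", "mirna_length", "promoter_up",
                        "promoter_down", "n_terms", "term_size",
                        "enriched_term_de"))
    check_number(cfg[[count_field]], count_field, lower = 0,
                 integer = TRUE)
  check_number(frac_de, "frac_de", lower = 0, upper = 1)
  check_number(planted_log2fc, "planted_log2fc", lower = 0)
  check_number(noise_sd, "noise_sd", lower = 1e-12)
  check_number(coexpr_target_r, "coexpr_target_r", lower = 0, upper = 1)
  check_number(genome_length_bp, "genome_length_bp", lower = 1)
  if (n_mrna < 1 || n_lncrna < 1)
    stop_domain("need at least one mRNA and one lncRNA probe")
  if (length(base_freq) != 4L || any(base_freq <= 0) ||
      abs(sum(base_freq) - 1) > 1e-8)
    stop_domain("'base_freq' must be 4 positive frequencies summing to 1")
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "simulation config: seed %d, %d-vs-%d design, %d mRNA / %d lncRNA / %d circRNA probes\n",
    x$seed, x$n_per_group, x$n_per_group, x$n_mrna, x$n_lncrna,
    x$n_circrna))
  cat(sprintf(
    "  frac_de %.2f, planted |log2 FC| %.1f, noise sd %.2f (log2), %d co-expressed pairs\n",
    x$frac_de, x$planted_log2fc, x$noise_sd, x$n_coexpr_pairs))
  invisible(x)
}

#' Read a simulation configuration from YAML or JSON
#'
#' The file holds a mapping whose keys mirror the [sim_config()]
#' argument names exactly.
#'
#' @param path file path (`.yaml`/`.yml` or `.json`).
#' @return a `sim_config` object.
#' @export
read_sim_config <- function(path) {
  vals <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  unknown <- setdiff(names(vals), names(formals(sim_config)))
  if (length(unknown) > 0)
    stop_domain("unknown config fields: ", paste(unknown, collapse = ", "))
  do.call(sim_config, vals)
}

#' @noRd
empty_truth <- function() {
  structure(list(
    de_ids_up = character(0),
    de_ids_down = character(0),
    coexpr_pairs = data.frame(nc_id = character(0),
                              coding_id = character(0),
                              sign = character(0),
                              stringsAsFactors = FALSE),
    category_by_lncrna = list(),
    cis_pairs = data.frame(lncrna_id = character(0),
                           gene_id = character(0),
                           distance_bp = numeric(0),
                           stringsAsFactors = FALSE),
    motif_sites = data.frame(tf = character(0), lncrna_id = character(0),
                             offset = integer(0), strand = character(0),
                             stringsAsFactors = FALSE),
    seed_sites = data.frame(mirna_id = character(0),
                            target_id = character(0), offset = integer(0),
                            site_type = character(0),
                            stringsAsFactors = FALSE),
    tf_targets = list(),
    enriched_term = NA_character_),
    class = "sim_truth")
}

#' @export
print.sim_truth <- function(x, ...) {
  cat("planted truth:\n")
  cat(sprintf("  DE: %d up, %d down\n", length(x$de_ids_up),
              length(x$de_ids_down)))
  cat(sprintf("  co-expressed pairs: %d\n", nrow(x$coexpr_pairs)))
  cat(sprintf("  classified lncRNAs: %d; cis pairs: %d\n",
              length(x$category_by_lncrna), nrow(x$cis_pairs)))
  cat(sprintf("  motif sites: %d; seed sites: %d; enriched term: %s\n",
              nrow(x$motif_sites), nrow(x$seed_sites), x$enriched_term))
  invisible(x)
}

#' @noRd
probe_ids_for <- function(config) {
  list(mrna = sprintf("MRNA%04d", seq_len(config$n_mrna)),
       lncrna = sprintf("LNC%04d", seq_len(config$n_lncrna)),
       circrna = if (config$n_circrna > 0)
         sprintf("CIRC%04d", seq_len(config$n_circrna)) else character(0))
}
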