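## Synthetic expression matrix with planted differential expression and
## planted co-expressed noncoding/coding pairs.
##
## Intensity model: linear intensity = 2^(baseline + group effect +
## noise), noise Normal(0, noise_sd) in log2 units. Baselines are
## uniform on [6, 12] log2 units (typical normalized microarray range);
## planted DE probes carry a +/- planted_log2fc shift in the case
## group; planted co-expressed pairs share a per-sample latent factor
## carrying a fraction coexpr_target_r of their noise variance.

#' Simulate the expression matrix and its planted truth
#'
#' @param config a [sim_config()].
#' @return list with `matrix` (an [expression_matrix()]) and `truth`
#'   (planted DE sets and co-expressed pairs).
#' @export
simulate_expression <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derive_seeds(config$seed, 4)[1L])
  ids <- probe_ids_for(config)
  probe_ids <- c(ids$mrna, ids$lncrna, ids$circrna)
  rna_type <- rep(c("mRNA", "lncRNA", "circRNA"),
                  c(config$n_mrna, config$n_lncrna, config$n_circrna))
  n <- 2L * config$n_per_group
  group <- rep(c("control", "case"), each = config$n_per_group)
  sample_ids <- c(sprintf("C%02d", seq_len(config$n_per_group)),
                  sprintf("B%02d", seq_len(config$n_per_group)))
  m <- length(probe_ids)
  truth <- empty_truth()

  baseline <- stats::runif(m, 6, 12)
  effect <- numeric(m)  # case-group shift in log2 units
  for (cls in c("mRNA", "lncRNA", "circRNA")) {
    i_cls <- which(rna_type == cls)
    n_de <- round(config$frac_de * length(i_cls))
    if (n_de == 0L) next
    de_idx <- sample(i_cls, n_de)
    n_up <- ceiling(n_de / 2)
    effect[de_idx[seq_len(n_up)]] <- config$planted_log2fc
    if (n_de > n_up)
      effect[de_idx[(n_up + 1L):n_de]] <- -config$planted_log2fc
  }

  ## choose planted pairs (among DE probes) and make the group effects
  ## sign-consistent with the pair sign before the matrix is formed
  pairs <- NULL
  if (config$n_coexpr_pairs > 0L) {
    de_idx <- which(effect != 0)
    nc_pool <- de_idx[rna_type[de_idx] != "mRNA"]
    co_pool <- de_idx[rna_type[de_idx] == "mRNA"]
    if (length(nc_pool) < config$n_coexpr_pairs ||
        length(co_pool) < config$n_coexpr_pairs)
      stop_domain("not enough planted DE probes for the requested ",
                  "co-expression pairs; raise frac_de or probe counts")
    i_nc <- sample(nc_pool, config$n_coexpr_pairs)
    i_co <- sample(co_pool, config$n_coexpr_pairs)
    signs <- rep(c("positive", "negative"),
                 length.out = config$n_coexpr_pairs)
    for (k in seq_len(config$n_coexpr_pairs)) {
      want_pos <- signs[k] == "positive"
      same_dir <- sign(effect[i_nc[k]]) == sign(effect[i_co[k]])
      if (want_pos != same_dir) effect[i_co[k]] <- -effect[i_co[k]]
    }
    pairs <- list(i_nc = i_nc, i_co = i_co, signs = signs)
  }

  noise <- matrix(stats::rnorm(m * n, sd = config$noise_sd), m, n)
  if (!is.null(pairs)) {
    ## pair members share a per-sample latent factor that carries a
    ## fraction rho of their noise variance; the within-group SD stays
    ## at noise_sd (so the planted DE effect is untouched) while the
    ## within-group correlation of the pair is rho and the pooled
    ## correlation, reinforced by the aligned group shift, is higher
    rho <- config$coexpr_target_r
    s_shared <- config$noise_sd * sqrt(rho)
    s_own <- config$noise_sd * sqrt(1 - rho)
    for (k in seq_along(pairs$signs)) {
      z <- stats::rnorm(n)
      pos <- pairs$signs[k] == "positive"
      noise[pairs$i_nc[k], ] <- s_shared * z + s_own * stats::rnorm(n)
      noise[pairs$i_co[k], ] <- (if (pos) 1 else -1) * s_shared * z +
        s_own * stats::rnorm(n)
    }
    truth$coexpr_pairs <- data.frame(
      nc_id = probe_ids[pairs$i_nc], coding_id = probe_ids[pairs$i_co],
      sign = pairs$signs, stringsAsFactors = FALSE)
  }
  log2v <- baseline + noise
  is_case <- group == "case"
  log2v[, is_case] <- log2v[, is_case] + effect

  truth$de_ids_up <- probe_ids[effect > 0]
  truth$de_ids_down <- probe_ids[effect < 0]

  mat <- expression_matrix(2^log2v, rna_type, group,
                           probe_ids = probe_ids,
                           sample_ids = sample_ids)
  list(matrix = mat, truth = truth)
}
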