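## Synthetic transcript and miRNA sequences with planted seed sites.
##
## Background sequence is iid over {A,C,G,U}. By default every chance
## occurrence of any generated miRNA's seed core is scrubbed (a core
## base is mutated) so that the planted seed-site truth is exhaustive;
## background-site statistics can be studied on raw sequences from
## random_rna() instead.

#' @noRd
plant_site <- function(seq, offset0, mirna, site_type, circular = FALSE) {
  ## writes the site for `mirna` of `site_type` at 0-based `offset0`
  ## (start of the full site); returns the modified sequence.
  m <- strsplit(mirna, "", fixed = TRUE)[[1L]]
  core <- revcomp_rna(paste(m[2:7], collapse = ""))
  m8 <- unname(COMPLEMENT[m[8L]])
  site <- switch(site_type,
                 "8mer" = paste0(m8, core, "A"),
                 "7mer_m8" = paste0(m8, core),
                 "7mer_A1" = paste0(core, "A"),
                 "6mer" = core,
                 stop_domain("unknown site_type"))
  L <- nchar(seq)
  if (nchar(site) > L) stop_domain("site longer than host sequence")
  if (!circular && offset0 + nchar(site) > L)
    stop_domain("site does not fit at the requested offset")
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  schars <- strsplit(site, "", fixed = TRUE)[[1L]]
  idx <- ((offset0 + seq_along(schars) - 1L) %% L) + 1L
  chars[idx] <- schars
  ## guard the flanks so the planted type is exactly the strongest type
  before <- if (offset0 >= 1L) offset0 else if (circular) L else NA
  after_raw <- offset0 + nchar(site) + 1L
  after <- if (after_raw <= L) after_raw else if (circular)
    ((after_raw - 1L) %% L) + 1L else NA
  fix_base <- function(i, forbid) {
    if (is.na(i)) return()
    if (chars[i] %in% forbid)
      chars[i] <<- setdiff(RNA_BASES, forbid)[1L]
  }
  if (site_type %in% c("6mer", "7mer_A1")) fix_base(before, m8)
  if (site_type %in% c("6mer", "7mer_m8")) fix_base(after, "A")
  paste(chars, collapse = "")
}

#' @noRd
scrub_seed_cores <- function(seqs, mirnas, keep_sites, circular_ids,
                             max_pass = 20L) {
  ## mutate chance seed-core matches (any miRNA, any sequence) that are
  ## not part of a planted site; keep_sites is a data frame
  ## (mirna_id, target_id, offset, site_type)
  cores <- vapply(mirnas, function(m) {
    ch <- strsplit(m, "", fixed = TRUE)[[1L]]
    revcomp_rna(paste(ch[2:7], collapse = ""))
  }, "")
  protected <- function(tid) {
    ks <- keep_sites[keep_sites$target_id == tid, , drop = FALSE]
    if (nrow(ks) == 0L) return(integer(0))
    L <- nchar(seqs[[tid]])
    unlist(lapply(seq_len(nrow(ks)), function(i) {
      len <- SITE_LENGTH[[ks$site_type[i]]]
      ## protect the site plus one flank base on each side (the type
      ## guards written by plant_site)
      (((ks$offset[i] - 1L) + 0:(len + 1L)) %% L) + 1L
    }))
  }
  for (tid in names(seqs)) {
    prot <- protected(tid)
    circ <- tid %in% circular_ids
    for (pass in seq_len(max_pass)) {
      s <- seqs[[tid]]
      L <- nchar(s)
      ext <- if (circ) paste0(s, substr(s, 1L, min(5L, L))) else s
      dirty <- FALSE
      for (core in cores) {
        from <- 1L
        repeat {
          i <- regexpr(core, substr(ext, from, nchar(ext)), fixed = TRUE)
          if (i == -1L) break
          st <- from + i - 1L
          from <- st + 1L
          if (st > L) break
          ## core occupies st..st+5 (wrapping); mutate its middle base
          ## unless every core base is protected
          pos <- ((st - 1L + 0:5) %% L) + 1L
          if (all(pos %in% prot)) next
          mut <- pos[!(pos %in% prot)][3L %% sum(!(pos %in% prot)) + 1L]
          old <- substr(s, mut, mut)
          substr(s, mut, mut) <- sample(setdiff(RNA_BASES, old), 1L)
          seqs[[tid]] <- s
          ext <- if (circ) paste0(s, substr(s, 1L, min(5L, L))) else s
          dirty <- TRUE
        }
      }
      if (!dirty) break
    }
  }
  seqs
}

#' Simulate transcript and miRNA sequences with planted seed sites
#'
#' Generates 3'UTR sequences for mRNAs, transcript sequences for
#' lncRNAs and (linearized) circRNAs, and miRNA sequences, then plants
#' miRNA seed-complementary sites: the first miRNA gets 8mer sites on
#' one lncRNA, one circRNA and three mRNAs (the ceRNA configuration);
#' the second miRNA gets an 8mer spanning a circRNA back-splice
#' junction; each further miRNA gets one site of a rotating type on a
#' further transcript. When DE truth is supplied, the ceRNA
#' configuration is planted on differentially expressed transcripts and
#' the remaining plants on non-DE transcripts.
#'
#' @param config a [sim_config()].
#' @param de_truth optional truth from [simulate_expression()]; used to
#'   pick planted hosts.
#' @return list with `sequences` (named list: `utr`, `lncrna`,
#'   `circrna`, `mirna`, each a named character vector) and `truth`
#'   (`seed_sites` data frame).
#' @export
simulate_sequences <- function(config, de_truth = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derive_seeds(config$seed, 4)[3L])
  if (config$n_mirna < 1L)
    return(list(sequences = list(utr = character(0),
                                 lncrna = character(0),
                                 circrna = character(0),
                                 mirna = character(0)),
                truth = empty_truth()))
  if (min(config$utr_length, config$lnc_seq_length,
          config$circ_seq_length) < 8L)
    stop_domain("site longer than host sequence: transcript sequences ",
                "must be at least 8 nt")
  ids <- probe_ids_for(config)
  gen <- function(id_vec, len)
    stats::setNames(vapply(id_vec, function(i)
      random_rna(len, config$base_freq), ""), id_vec)
  utr <- gen(ids$mrna, config$utr_length)
  lnc <- gen(ids$lncrna, config$lnc_seq_length)
  circ <- gen(ids$circrna, config$circ_seq_length)
  mirna <- stats::setNames(
    vapply(seq_len(config$n_mirna), function(i)
      random_rna(config$mirna_length, config$base_freq), ""),
    sprintf("MIR%03d", seq_len(config$n_mirna)))

  de_all <- if (!is.null(de_truth))
    c(de_truth$de_ids_up, de_truth$de_ids_down) else character(0)
  pick <- function(pool_ids, n, de = TRUE) {
    pool <- if (de) intersect(pool_ids, de_all) else
      setdiff(pool_ids, de_all)
    if (length(pool) < n)
      stop_domain("not enough ", if (de) "DE " else "non-DE ",
                  "transcripts to plant the requested seed sites")
    pool[seq_len(n)]
  }
  truth <- empty_truth()
  sites <- list()
  add_site <- function(mid, tid, offset, type)
    sites[[length(sites) + 1L]] <<- data.frame(
      mirna_id = mid, target_id = tid, offset = offset, site_type = type,
      stringsAsFactors = FALSE)

  use_de <- !is.null(de_truth) && length(de_all) > 0
  ## ceRNA configuration: miRNA 1 with 8mers on 1 lncRNA, 1 circRNA,
  ## 3 mRNAs
  m1 <- names(mirna)[1L]
  host_lnc <- pick(ids$lncrna, 1, de = use_de)
  host_mrna <- pick(ids$mrna, 3, de = use_de)
  add_site(m1, host_lnc, 40L, "8mer")
  lnc[[host_lnc]] <- plant_site(lnc[[host_lnc]], 40L, mirna[[m1]], "8mer")
  for (k in seq_along(host_mrna)) {
    off <- 30L * k
    add_site(m1, host_mrna[k], off, "8mer")
    utr[[host_mrna[k]]] <- plant_site(utr[[host_mrna[k]]], off,
                                      mirna[[m1]], "8mer")
  }
  if (config$n_circrna > 0L) {
    host_circ <- pick(ids$circrna, 1, de = use_de)
    add_site(m1, host_circ, 40L, "8mer")
    circ[[host_circ]] <- plant_site(circ[[host_circ]], 40L, mirna[[m1]],
                                    "8mer")
    ## junction-spanning site on a (non-DE if possible) circRNA
    if (config$n_mirna >= 2L) {
      m2 <- names(mirna)[2L]
      jc <- tryCatch(pick(ids$circrna, 1, de = FALSE),
                     error = function(e) host_circ)
      joff <- nchar(circ[[jc]]) - 4L   # 8-nt site wraps 4 bases
      circ[[jc]] <- plant_site(circ[[jc]], joff, mirna[[m2]], "8mer",
                               circular = TRUE)
      add_site(m2, jc, joff, "8mer")
    }
  }
  ## rotating-type plants for the remaining miRNAs on non-DE hosts
  if (config$n_mirna >= 3L) {
    types <- c("6mer", "7mer_A1", "7mer_m8", "8mer")
    hosts <- tryCatch(pick(ids$mrna, config$n_mirna - 2L, de = FALSE),
                      error = function(e) character(0))
    for (j in seq_along(hosts)) {
      mj <- names(mirna)[j + 2L]
      ty <- types[(j - 1L) %% 4L + 1L]
      add_site(mj, hosts[j], 100L, ty)
      utr[[hosts[j]]] <- plant_site(utr[[hosts[j]]], 100L, mirna[[mj]], ty)
    }
  }
  truth$seed_sites <- do.call(rbind, sites)

  seqs <- c(as.list(utr), as.list(lnc), as.list(circ))
  if (config$scrub_background)
    seqs <- scrub_seed_cores(seqs, mirna, truth$seed_sites, ids$circrna)
  n_utr <- length(utr); n_lnc <- length(lnc)
  list(sequences = list(
         utr = unlist(seqs[seq_len(n_utr)]),
         lncrna = unlist(seqs[n_utr + seq_len(n_lnc)]),
         circrna = if (length(circ) > 0)
           unlist(seqs[n_utr + n_lnc + seq_along(circ)]) else character(0),
         mirna = mirna),
       truth = truth)
}
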