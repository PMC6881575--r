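## Network export for graph tools (Cytoscape and friends): SIF with
## relation tags encoding edge semantics, GraphML with typed edge
## attributes (via igraph), and plain TSV.

#' Canonical edge table of any network object
#'
#' Normalizes the package's network objects to a `from`, `to`,
#' `relation` edge data frame (plus numeric/character attribute
#' columns). CNC edges carry `pos_corr`/`neg_corr` relations (negative
#' correlations are the dashed-edge semantic in figures), TF-lncRNA
#' edges `tf_binds`, ceRNA edges `mirna_site`, pathway-gene edges
#' `term_member`.
#'
#' @param x a `cnc_network`, `tf_network`, `cerna_network`, ternary
#'   triple table, or pathway-gene edge table.
#' @return data frame with `from`, `to`, `relation` and attributes.
#' @export
network_edges <- function(x) {
  if (inherits(x, "cnc_network")) {
    data.frame(from = x$nc_id, to = x$coding_id,
               relation = ifelse(x$sign == "negative", "neg_corr",
                                 "pos_corr"),
               r = x$r, p = x$p, q = x$q, sign = x$sign,
               stringsAsFactors = FALSE)
  } else if (inherits(x, "tf_network")) {
    data.frame(from = x$edges$tf, to = x$edges$lncrna_id,
               relation = rep("tf_binds", nrow(x$edges)),
               stringsAsFactors = FALSE)
  } else if (inherits(x, "cerna_network")) {
    data.frame(from = x$edges$from, to = x$edges$to,
               relation = rep("mirna_site", nrow(x$edges)),
               edge_kind = x$edges$relation, stringsAsFactors = FALSE)
  } else if (is.data.frame(x) &&
             all(c("term_id", "gene_id") %in% names(x))) {
    data.frame(from = x$term_id, to = x$gene_id,
               relation = rep("term_member", nrow(x)),
               stringsAsFactors = FALSE)
  } else if (is.data.frame(x) &&
             all(c("from", "to", "relation") %in% names(x))) {
    x
  } else stop_domain("unsupported network object")
}

#' Export a network for external graph tools
#'
#' @param x a network object (see [network_edges()]) or a canonical
#'   edge data frame.
#' @param path output file.
#' @param format `"SIF"` (node relation node lines), `"GraphML"`
#'   (typed edge attributes, loadable by igraph/Cytoscape), or `"TSV"`.
#' @return `path`, invisibly.
#' @export
export_network <- function(x, path, format = c("SIF", "GraphML", "TSV")) {
  format <- match.arg(format)
  edges <- network_edges(x)
  if (format == "SIF") {
    lines <- if (nrow(edges) > 0)
      paste(edges$from, edges$relation, edges$to, sep = "\t")
    else character(0)
    writeLines(lines, path)
  } else if (format == "TSV") {
    utils::write.table(edges, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    g <- igraph::graph_from_data_frame(
      if (nrow(edges) > 0) edges else
        data.frame(from = character(0), to = character(0)),
      directed = FALSE)
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' Read back an exported network
#'
#' @param path file written by [export_network()].
#' @param format `"SIF"`, `"GraphML"` or `"TSV"`.
#' @return for SIF/TSV a data frame; for GraphML an igraph graph.
#' @export
read_network <- function(path, format = c("SIF", "GraphML", "TSV")) {
  format <- match.arg(format)
  if (format == "SIF") {
    lines <- readLines(path)
    if (length(lines) == 0)
      return(data.frame(from = character(0), relation = character(0),
                        to = character(0), stringsAsFactors = FALSE))
    parts <- do.call(rbind, strsplit(lines, "\t", fixed = TRUE))
    data.frame(from = parts[, 1], relation = parts[, 2], to = parts[, 3],
               stringsAsFactors = FALSE)
  } else if (format == "TSV") {
    utils::read.delim(path, stringsAsFactors = FALSE)
  } else {
    igraph::read_graph(path, format = "graphml")
  }
}
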