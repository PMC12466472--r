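#' Distance-matrix TSV round trip
#'
#' Square symmetric matrix with sample ids in the first column and header.
#'
#' @param D a `distance_matrix`.
#' @param path file path.
#' @export
write_distance_tsv <- function(D, path) {
  m <- dist_values(D)
  df <- data.frame(sample_id = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_distance_tsv
#' @export
read_distance_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  as_dist_matrix(m, df[[1]])
}

#' Write a GRM as TSV
#'
#' @param grm a `grm` object.
#' @param path file path.
#' @export
write_grm_tsv <- function(grm, path) {
  m <- grm_values(grm)
  df <- data.frame(sample_id = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' GWAS summary-statistics TSV round trip
#'
#' Columns: snp, beta, se, p (extra columns preserved on read).
#'
#' @param stats data.frame (e.g. the `table` of a `gwas_result`).
#' @param path file path.
#' @export
write_summary_stats <- function(stats, path) {
  utils::write.table(stats, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_summary_stats
#' @export
read_summary_stats <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  stopifnot(all(c("snp", "beta", "se") %in% names(df)))
  df
}

#' Export a co-occurrence network
#'
#' Edge list TSV (a, b, r, p, q) or GraphML via igraph.
#'
#' @param net a `co_network`.
#' @param path file path.
#' @export
write_network_edges_tsv <- function(net, path) {
  utils::write.table(net$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_network_edges_tsv
#' @export
write_network_graphml <- function(net, path) {
  g <- net_igraph(net)
  igraph::E(g)$r <- net$edges$r
  igraph::E(g)$q <- net$edges$q
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Write a colocalization result as JSON
#'
#' @param res a `coloc_result`.
#' @param path file path.
#' @export
write_coloc_json <- function(res, path) {
  jsonlite::write_json(list(pp = as.list(res$pp), n_snps = res$n_snps,
                            priors = as.list(res$priors),
                            shared_call = res$shared_call),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
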