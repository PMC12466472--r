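#' Select genera eligible for network construction
#'
#' Keeps genera present in at least `prevalence_min` of the stratum's
#' samples AND with mean relative abundance strictly greater than
#' `mean_rel_min`. Applied per enterotype stratum, so the two node sets may
#' differ.
#'
#' @param tab an [abundance_table()] (already subset to the stratum).
#' @param prevalence_min minimum prevalence (default 0.50, inclusive).
#' @param mean_rel_min mean relative-abundance floor (default 0.001,
#'   exclusive).
#' @return character vector of genus ids.
#' @export
select_network_genera <- function(tab, prevalence_min = 0.50,
                                  mean_rel_min = 0.001) {
  rel <- rel_abundance(tab)
  if (nrow(rel) == 0) stop("empty table")
  prev <- colMeans(rel > 0)
  mu <- colMeans(rel)
  keep <- prev >= prevalence_min & mu > mean_rel_min
  if (!any(keep)) stop("no genus passes the network filters")
  colnames(rel)[keep]
}

#' Spearman partial correlation matrix
#'
#' Rank-transforms each genus, computes the rank (Spearman) correlation
#' matrix, and obtains each pair's partial correlation controlling for all
#' other retained genera from the inverse (or Moore-Penrose pseudo-inverse,
#' with a warning, when singular or when samples are too few):
#' `r_ij = -P_ij / sqrt(P_ii P_jj)`. P-values use the t approximation with
#' `df = n - g`, where `g` = conditioning-set size + 2 = number of genera.
#'
#' @param X samples x genera matrix (relative abundances) or
#'   [abundance_table()].
#' @return list with `r` (partial correlations, unit diagonal), `p`, `n`,
#'   `df`.
#' @export
spearman_partial_matrix <- function(X) {
  X <- rel_abundance(X)
  n <- nrow(X); m <- ncol(X)
  R <- apply(X, 2, rank)
  C <- stats::cor(R)
  P <- tryCatch({
    if (n <= m + 2) stop("low rank")
    solve(C)
  }, error = function(e) {
    warning("singular rank-correlation matrix: using pseudo-inverse")
    MASS::ginv(C)
  })
  d <- sqrt(abs(diag(P)))
  r <- -P / tcrossprod(d)
  diag(r) <- 1
  r <- pmin(pmax(r, -1), 1)
  dimnames(r) <- dimnames(C)
  df <- n - m
  tstat <- r * sqrt(pmax(df, 1) / pmax(1 - r^2, 1e-300))
  p <- 2 * stats::pt(-abs(tstat), df = max(df, 1))
  diag(p) <- NA
  list(r = r, p = p, n = n, df = df)
}

#' Build a co-occurrence network from correlation and p matrices
#'
#' BH-adjusts the upper-triangle p-values and keeps edges with `q <= fdr`.
#' Nodes are the genera incident to at least one retained edge.
#'
#' @param r,p square symmetric matrices (e.g. from
#'   [spearman_partial_matrix()]).
#' @param fdr FDR level (default 0.05).
#' @param label optional enterotype label carried in the result.
#' @return `co_network`: list with `label`, `nodes`, `edges` (data.frame
#'   a, b, r, p, q with `a < b`), `n_tested`.
#' @export
build_network <- function(r, p, fdr = 0.05, label = NULL) {
  stopifnot(all(dim(r) == dim(p)))
  ids <- colnames(r)
  ut <- which(upper.tri(r), arr.ind = TRUE)
  edges <- data.frame(a = ids[ut[, 1]], b = ids[ut[, 2]],
                      r = r[ut], p = p[ut], stringsAsFactors = FALSE)
  swap <- edges$a > edges$b
  tmp <- edges$a[swap]; edges$a[swap] <- edges$b[swap]; edges$b[swap] <- tmp
  edges$q <- bh_adjust(edges$p)
  keep <- !is.na(edges$q) & edges$q <= fdr
  edges <- edges[keep, , drop = FALSE]
  edges <- edges[order(edges$a, edges$b), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(label = label,
                 nodes = sort(unique(c(edges$a, edges$b))),
                 edges = edges, n_tested = nrow(ut)),
            class = "co_network")
}

#' @export
print.co_network <- function(x, ...) {
  cat(sprintf("co_network%s: %d nodes, %d edges (of %d tested pairs)\n",
              if (is.null(x$label)) "" else paste0(" [", x$label, "]"),
              length(x$nodes), nrow(x$edges), x$n_tested))
  invisible(x)
}

net_igraph <- function(net) {
  igraph::graph_from_data_frame(net$edges[, c("a", "b")], directed = FALSE,
                                vertices = data.frame(name = net$nodes))
}

#' Topology of a co-occurrence network
#'
#' Global clustering coefficient (transitivity), average shortest-path
#' distance over the largest connected component, normalized betweenness
#' (mean and per node) and per-node degree.
#'
#' @param net a `co_network`.
#' @return list with `n_vertices`, `n_edges`, `clustering_coefficient`,
#'   `average_distance`, `average_betweenness`, `degree`, `betweenness`.
#' @export
network_topology <- function(net) {
  if (nrow(net$edges) == 0) {
    return(list(n_vertices = length(net$nodes), n_edges = 0L,
                clustering_coefficient = NA_real_,
                average_distance = NA_real_, average_betweenness = NA_real_,
                degree = NULL, betweenness = NULL))
  }
  g <- net_igraph(net)
  comp <- igraph::components(g)
  big <- igraph::induced_subgraph(
    g, which(comp$membership == which.max(comp$csize)))
  deg <- igraph::degree(g)
  btw <- igraph::betweenness(g, normalized = TRUE)
  list(n_vertices = igraph::vcount(g),
       n_edges = igraph::ecount(g),
       clustering_coefficient = igraph::transitivity(g, type = "global"),
       average_distance = igraph::mean_distance(big),
       average_betweenness = mean(btw),
       degree = deg, betweenness = btw)
}

#' Generalist / specialist edge taxonomy across two networks
#'
#' Pairs significant in exactly one network are specialists of that
#' enterotype; pairs significant in both are generalists, subdivided into
#' `direction_change` (opposite correlation signs), `strength_change` (same
#' sign, correlation difference above `strength_delta`) and `stable`.
#' Direction change takes precedence, so the three classes partition the
#' generalist set. By default the strength criterion compares signed
#' coefficients (`|r_E1 - r_E2|`); set `on_signed = FALSE` for the
#' absolute-magnitude reading (`||r_E1| - |r_E2||`).
#'
#' @param netE1,netE2 `co_network` objects from the two strata.
#' @param strength_delta threshold for a strength change (default 0.2,
#'   strict).
#' @param on_signed compare signed coefficients (default TRUE).
#' @return data.frame: a, b, r_E1, r_E2, status, generalist_class
#'   (NA unless status == "generalist").
#' @export
classify_generalist_edges <- function(netE1, netE2, strength_delta = 0.2,
                                      on_signed = TRUE) {
  key1 <- paste(netE1$edges$a, netE1$edges$b, sep = "\r")
  key2 <- paste(netE2$edges$a, netE2$edges$b, sep = "\r")
  all_keys <- sort(unique(c(key1, key2)))
  ab <- do.call(rbind, strsplit(all_keys, "\r", fixed = TRUE))
  r1 <- netE1$edges$r[match(all_keys, key1)]
  r2 <- netE2$edges$r[match(all_keys, key2)]
  status <- ifelse(!is.na(r1) & !is.na(r2), "generalist",
                   ifelse(!is.na(r1), "specialist_E1", "specialist_E2"))
  gen_class <- rep(NA_character_, length(all_keys))
  gi <- status == "generalist"
  if (any(gi)) {
    opp <- sign(r1[gi]) * sign(r2[gi]) < 0
    delta <- if (on_signed) abs(r1[gi] - r2[gi]) else abs(abs(r1[gi]) - abs(r2[gi]))
    gen_class[gi] <- ifelse(opp, "direction_change",
                            ifelse(delta > strength_delta,
                                   "strength_change", "stable"))
  }
  data.frame(a = ab[, 1], b = ab[, 2], r_E1 = r1, r_E2 = r2,
             status = status, generalist_class = gen_class,
             stringsAsFactors = FALSE)
}

#' Node sign profile and key taxa
#'
#' For every node: counts of positive- and negative-correlation incident
#' edges (they sum to the degree) and `log10(neg/pos)` (`NA` when either
#' count is zero). Key taxa are the `top_n` nodes by degree, ties broken
#' alphabetically.
#'
#' @param net a `co_network`.
#' @param top_n number of key taxa (default 10).
#' @return list with `profile` (data.frame: node, degree, n_pos, n_neg,
#'   log10_neg_pos) and `key_taxa` (character).
#' @export
node_sign_profile_and_key_taxa <- function(net, top_n = 10L) {
  nodes <- net$nodes
  e <- net$edges
  n_pos <- n_neg <- stats::setNames(integer(length(nodes)), nodes)
  for (i in seq_len(nrow(e))) {
    tgt <- if (e$r[i] >= 0) "pos" else "neg"
    if (tgt == "pos") {
      n_pos[e$a[i]] <- n_pos[e$a[i]] + 1L; n_pos[e$b[i]] <- n_pos[e$b[i]] + 1L
    } else {
      n_neg[e$a[i]] <- n_neg[e$a[i]] + 1L; n_neg[e$b[i]] <- n_neg[e$b[i]] + 1L
    }
  }
  degree <- n_pos + n_neg
  prof <- data.frame(node = nodes, degree = as.integer(degree),
                     n_pos = as.integer(n_pos), n_neg = as.integer(n_neg),
                     log10_neg_pos = ifelse(n_pos > 0 & n_neg > 0,
                                            log10(n_neg / n_pos), NA_real_),
                     stringsAsFactors = FALSE)
  ord <- order(-prof$degree, prof$node)
  list(profile = prof[ord, ],
       key_taxa = prof$node[ord][seq_len(min(top_n, length(nodes)))])
}
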