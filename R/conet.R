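# Co-occurrence network construction: abundance filter, Spearman
# correlations with BH-FDR control, igraph assembly, and the topology panel.

#' Filter OTUs by total relative abundance
#'
#' Keeps OTUs whose share of all reads in the table exceeds `threshold`
#' (default 0.1%), the usual pre-filter before correlation-network
#' construction.
#'
#' @param table an [otu_table()].
#' @param threshold minimum total relative abundance (fraction, not percent).
#' @return filtered [otu_table()]; kept/dropped counts are messaged.
#' @export
filter_otus <- function(table, threshold = 0.001) {
  tab <- unclass(table)
  rel <- colSums(tab) / sum(tab)
  keep <- rel > threshold
  if (!any(keep))
    stop("no OTU exceeds total relative abundance ", threshold,
         "; lower the threshold")
  message(sprintf("abundance filter: kept %d of %d OTUs", sum(keep),
                  length(keep)))
  otu_table(tab[, keep, drop = FALSE])
}

#' Candidate correlation edges between OTUs
#'
#' Computes Spearman correlations (average ranks for ties, p from the t
#' approximation) between all OTU pairs on per-sample relative abundances,
#' applies Benjamini-Hochberg adjustment across all tested pairs, and keeps
#' pairs with `|r| > r_threshold` and adjusted p < `alpha`. OTUs with
#' constant abundance have undefined correlations; their pairs are excluded
#' and counted.
#'
#' @param table an [otu_table()] with >= 5 samples.
#' @param r_threshold absolute correlation cutoff (strict inequality).
#' @param alpha significance level on the (adjusted) p-value.
#' @param adjust use the BH-adjusted p-value (set `FALSE` to reproduce the
#'   unadjusted variant).
#' @param use_relative correlate relative abundances (default) or raw counts.
#' @return data.frame: otu_a, otu_b, r, p, q, sign (+1/-1), with attributes
#'   `n_tested` and `n_constant_excluded`.
#' @export
correlation_edges <- function(table, r_threshold = 0.6, alpha = 0.05,
                              adjust = TRUE, use_relative = TRUE) {
  tab <- unclass(table)
  if (nrow(tab) < 5L) stop("need at least 5 samples for rank correlations")
  if (ncol(tab) < 2L) stop("need at least 2 OTUs")
  x <- if (use_relative) tab / rowSums(tab) else tab
  constant <- apply(x, 2, function(v) length(unique(v)) == 1L)
  n_samp <- nrow(x)
  r <- suppressWarnings(cor(x, method = "spearman"))
  ut <- which(upper.tri(r), arr.ind = TRUE)
  rv <- r[ut]
  ok <- !constant[ut[, 1]] & !constant[ut[, 2]] & is.finite(rv)
  n_excluded <- sum(!ok)
  ut <- ut[ok, , drop = FALSE]
  rv <- rv[ok]
  # t approximation, consistent with cor.test(exact = FALSE)
  tt <- rv * sqrt((n_samp - 2) / pmax(1 - rv^2, .Machine$double.eps))
  pv <- 2 * pt(-abs(tt), df = n_samp - 2)
  qv <- bh_adjust(pv)
  keep <- abs(rv) > r_threshold & (if (adjust) qv else pv) < alpha
  edges <- data.frame(otu_a = colnames(x)[ut[, 1]][keep],
                      otu_b = colnames(x)[ut[, 2]][keep],
                      r = rv[keep], p = pv[keep], q = qv[keep],
                      sign = ifelse(rv[keep] > 0, 1L, -1L))
  attr(edges, "n_tested") <- length(rv)
  attr(edges, "n_constant_excluded") <- n_excluded
  edges
}

#' Assemble a co-occurrence graph from candidate edges
#'
#' Builds a simple undirected graph (duplicate pairs collapse to one edge,
#' self-loops dropped); nodes with no surviving edge are excluded. Edge
#' `weight` is the correlation, `sign` its sign; node attributes carry an
#' optional phylum and the mean relative abundance when a table is supplied.
#'
#' @param edges data.frame from [correlation_edges()].
#' @param table optional [otu_table()] for node abundance attributes.
#' @param phylum optional named character vector OTU -> phylum; unknown OTUs
#'   get `"unknown"`.
#' @return an [igraph::igraph].
#' @export
build_network <- function(edges, table = NULL, phylum = NULL) {
  if (nrow(edges) == 0L) {
    g <- igraph::make_empty_graph(0, directed = FALSE)
    return(g)
  }
  g <- igraph::graph_from_data_frame(
    data.frame(from = edges$otu_a, to = edges$otu_b,
               weight = edges$r, q = edges$q, sign = edges$sign),
    directed = FALSE)
  g <- igraph::simplify(g, edge.attr.comb = "first")
  nm <- igraph::V(g)$name
  ph <- rep("unknown", length(nm))
  if (!is.null(phylum)) {
    hit <- nm %in% names(phylum)
    ph[hit] <- phylum[nm[hit]]
  }
  g <- igraph::set_vertex_attr(g, "phylum", value = ph)
  if (!is.null(table)) {
    rel <- colMeans(unclass(table) / rowSums(unclass(table)))
    g <- igraph::set_vertex_attr(g, "mean_rel_abund",
                                 value = unname(rel[nm]))
  }
  g
}

#' Topology-metric panel for a co-occurrence network
#'
#' Reports node and edge counts, average degree, global transitivity
#' (3 x triangles / connected triples), average local clustering coefficient
#' (isolated or degree-1 nodes count 0), average path length and diameter on
#' the largest connected component, greedy-optimization modularity, graph
#' density, and the percentage of positive edges.
#'
#' @param graph an [igraph::igraph] from [build_network()].
#' @param modularity_seed seed for the community search (the greedy algorithm
#'   is deterministic; the seed is fixed for reproducibility of any tie
#'   handling).
#' @return one-row data.frame in the conventional column order; path metrics
#'   are `NA` for empty graphs, and `on_largest_component` flags a
#'   disconnected graph.
#' @export
topology <- function(graph, modularity_seed = 1L) {
  n <- igraph::vcount(graph)
  e <- igraph::ecount(graph)
  if (n == 0L) {
    return(data.frame(nodes = 0L, edges = 0L, average_degree = NA_real_,
                      average_transitivity = NA_real_,
                      average_clustering_coefficient = NA_real_,
                      average_path_length = NA_real_, diameter = NA_real_,
                      modularity = NA_real_, graph_density = NA_real_,
                      positive_relationship_pct = NA_real_,
                      on_largest_component = FALSE))
  }
  gu <- graph # unweighted view for the topology metrics
  if ("weight" %in% igraph::edge_attr_names(gu))
    gu <- igraph::delete_edge_attr(gu, "weight")
  comp <- igraph::components(gu)
  giant <- igraph::induced_subgraph(
    gu, which(comp$membership == which.max(comp$csize)))
  set.seed(modularity_seed)
  mod <- if (e > 0) {
    cl <- igraph::cluster_fast_greedy(gu)
    igraph::modularity(gu, igraph::membership(cl))
  } else NA_real_
  pos_pct <- if (e > 0) 100 * sum(igraph::E(graph)$sign > 0) / e else NA_real_
  data.frame(
    nodes = n, edges = e,
    average_degree = 2 * e / n,
    average_transitivity = igraph::transitivity(gu, type = "global"),
    average_clustering_coefficient =
      mean(igraph::transitivity(gu, type = "local", isolates = "zero")),
    average_path_length = igraph::mean_distance(giant, directed = FALSE),
    diameter = igraph::diameter(giant, directed = FALSE, weights = NA),
    modularity = mod,
    graph_density = if (n > 1) 2 * e / (n * (n - 1)) else NA_real_,
    positive_relationship_pct = pos_pct,
    on_largest_component = comp$no > 1L)
}

#' Keystone nodes by degree (convention, not a definition from first
#' principles): the top `top_frac` of nodes by degree.
#'
#' @param graph an [igraph::igraph].
#' @param top_frac fraction of nodes to report (default 1%).
#' @return character vector of node names.
#' @export
keystone_nodes <- function(graph, top_frac = 0.01) {
  if (igraph::vcount(graph) == 0L) return(character())
  deg <- igraph::degree(graph)
  k <- max(1L, ceiling(top_frac * length(deg)))
  names(sort(deg, decreasing = TRUE))[seq_len(k)]
}
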