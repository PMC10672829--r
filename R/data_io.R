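#' Construct and validate an OTU table
#'
#' An OTU table is an integer matrix of read counts with samples as rows and
#' OTUs as columns; row names are sample identifiers, column names are OTU
#' identifiers. This constructor validates the invariants every downstream
#' operation relies on: unique identifiers, non-negative integer counts, and
#' no all-zero samples. All-zero OTU columns are permitted (they arise from
#' rarefaction and subsetting) and are recorded in the `"zero_otus"`
#' attribute.
#'
#' @param counts numeric matrix of counts, samples x OTUs.
#' @param sample_ids,otu_ids optional identifier vectors; default to the
#'   dimnames of `counts`.
#' @return the validated integer matrix with class `"otu_table"`.
#' @export
otu_table <- function(counts, sample_ids = rownames(counts),
                      otu_ids = colnames(counts)) {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(nrow(counts)))
  if (is.null(otu_ids)) otu_ids <- paste0("OTU_", seq_len(ncol(counts)))
  if (anyDuplicated(sample_ids))
    stop("duplicate sample identifiers: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  if (anyDuplicated(otu_ids))
    stop("duplicate OTU identifiers: ",
         paste(unique(otu_ids[duplicated(otu_ids)]), collapse = ", "))
  if (anyNA(counts)) stop("OTU table contains missing values")
  if (any(counts < 0)) stop("OTU table contains negative counts")
  if (any(abs(counts - round(counts)) > 1e-8))
    stop("OTU table contains non-integer counts")
  storage.mode(counts) <- "integer"
  dimnames(counts) <- list(sample_ids, otu_ids)
  zero_samples <- rownames(counts)[rowSums(counts) == 0L]
  if (length(zero_samples))
    stop("all-zero sample row(s): ", paste(zero_samples, collapse = ", "))
  attr(counts, "zero_otus") <- colnames(counts)[colSums(counts) == 0L]
  class(counts) <- c("otu_table", class(counts))
  counts
}

#' Read an OTU table from a tab-separated file
#'
#' The on-disk orientation is samples x OTUs (first column holds sample
#' identifiers). Many tools emit the transpose; set `taxa_as_rows = TRUE` to
#' transpose on read rather than guessing.
#'
#' @param path path to a TSV file.
#' @param taxa_as_rows if `TRUE`, the file holds OTUs as rows and samples as
#'   columns and is transposed on read.
#' @return an [otu_table()].
#' @export
read_otu_table <- function(path, taxa_as_rows = FALSE) {
  raw <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                    colClasses = "character")
  if (ncol(raw) < 2L) stop("OTU table file needs an id column plus counts: ", path)
  ids <- raw[[1L]]
  otu_ids <- colnames(raw)[-1L] # before subsetting, which make.unique()s names
  cells <- as.matrix(raw[, -1L, drop = FALSE])
  colnames(cells) <- otu_ids
  num <- suppressWarnings(as.numeric(cells))
  bad <- which(is.na(num) | abs(num - round(num)) > 1e-8)
  if (length(bad)) {
    i <- ((bad[1L] - 1L) %% nrow(cells)) + 1L
    j <- ((bad[1L] - 1L) %/% nrow(cells)) + 1L
    stop(sprintf("non-integer cell at data row %d, column '%s' (value '%s')",
                 i, colnames(cells)[j], cells[bad[1L]]))
  }
  m <- matrix(as.integer(num), nrow = nrow(cells),
              dimnames = list(ids, colnames(cells)))
  if (taxa_as_rows) m <- t(m)
  tab <- otu_table(m)
  message(sprintf("read OTU table: %d samples x %d OTUs", nrow(tab), ncol(tab)))
  tab
}

#' Write an OTU table to a tab-separated file
#'
#' Inverse of [read_otu_table()]: samples as rows, first column `sample_id`.
#'
#' @param table an [otu_table()].
#' @param path output path.
#' @export
write_otu_table <- function(table, path) {
  df <- data.frame(sample_id = rownames(table), as.data.frame(unclass(table)),
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.habitats <- c("water", "sediment")
.treatments <- c("C", "T", "H")
.seasons <- c("spring", "summer", "autumn", "winter")

#' Read / write the sample metadata table
#'
#' The metadata CSV has fixed leading columns `sample_id`, `habitat`
#' (water/sediment), `treatment` (C = control, T = constant warming,
#' H = heatwave), `season`, `tank`, followed by environmental covariates.
#' Missing covariates are allowed (sediment samples lack water-column
#' variables and vice versa); operations that need a covariate fail fast
#' naming it.
#'
#' @param path CSV path.
#' @return a data.frame with validated design factors.
#' @export
read_sample_frame <- function(path) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  validate_sample_frame(df)
}

#' @rdname read_sample_frame
#' @param frame a sample metadata data.frame.
#' @export
write_sample_frame <- function(frame, path) {
  write.csv(frame, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname read_sample_frame
#' @export
validate_sample_frame <- function(frame) {
  need <- c("sample_id", "habitat", "treatment", "season", "tank")
  miss <- setdiff(need, names(frame))
  if (length(miss)) stop("metadata lacks column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(frame$sample_id))
    stop("duplicate sample_id in metadata: ",
         paste(unique(frame$sample_id[duplicated(frame$sample_id)]), collapse = ", "))
  chk <- function(col, allowed) {
    bad <- setdiff(unique(frame[[col]]), allowed)
    if (length(bad))
      stop(sprintf("invalid %s value(s): %s (allowed: %s)", col,
                   paste(bad, collapse = ", "), paste(allowed, collapse = ", ")))
  }
  chk("habitat", .habitats)
  chk("treatment", .treatments)
  chk("season", .seasons)
  frame
}

#' Read a phylogenetic tree from a newick file
#'
#' @param path newick file path.
#' @param default_branch_length value to assign when the file carries no
#'   branch lengths; by default missing lengths are an error.
#' @return an [ape::phylo] tree with non-negative branch lengths.
#' @export
read_tree <- function(path, default_branch_length = NULL) {
  tree <- tryCatch(ape::read.tree(path), error = function(e)
    stop("failed to parse newick file '", path, "': ", conditionMessage(e)))
  if (is.null(tree)) stop("failed to parse newick file: ", path)
  if (is.null(tree$edge.length)) {
    if (is.null(default_branch_length))
      stop("tree has no branch lengths and no default was supplied: ", path)
    tree$edge.length <- rep(default_branch_length, nrow(tree$edge))
  }
  if (anyNA(tree$edge.length) || any(tree$edge.length < 0))
    stop("tree has missing or negative branch lengths: ", path)
  tree
}

#' Patristic (tip-to-tip) distance matrix
#'
#' Sums branch lengths along the path between every pair of requested tips.
#'
#' @param tree an [ape::phylo] tree with branch lengths.
#' @param otu_ids tips to keep, in order; defaults to all tips.
#' @return symmetric numeric matrix with zero diagonal, dimnames = `otu_ids`.
#' @export
patristic_distances <- function(tree, otu_ids = tree$tip.label) {
  miss <- setdiff(otu_ids, tree$tip.label)
  if (length(miss))
    stop("OTU(s) missing from tree: ", paste(miss, collapse = ", "))
  D <- ape::cophenetic.phylo(tree)
  D[otu_ids, otu_ids, drop = FALSE]
}

#' Cross-validate an OTU table, metadata and tree
#'
#' Checks that every sample in the table has exactly one metadata row and
#' (when `phylo = TRUE`) that every OTU is a tip of the tree, reporting the
#' complete list of offenders. The tree's tip set may exceed the OTU set:
#' extra tips are pruned on demand by phylogenetic operations.
#'
#' @param table an [otu_table()].
#' @param frame optional sample metadata.
#' @param tree optional phylogeny.
#' @param phylo require full tip coverage of the OTU set.
#' @return invisibly `TRUE`; errors list all inconsistent identifiers.
#' @export
validate_dataset <- function(table, frame = NULL, tree = NULL, phylo = FALSE) {
  if (!is.null(frame)) {
    validate_sample_frame(frame)
    miss <- setdiff(rownames(table), frame$sample_id)
    if (length(miss))
      stop("samples absent from metadata: ", paste(miss, collapse = ", "))
  }
  if (!is.null(tree) && phylo) {
    miss <- setdiff(colnames(table), tree$tip.label)
    if (length(miss))
      stop("OTUs absent from tree: ", paste(miss, collapse = ", "))
  }
  invisible(TRUE)
}

#' Export a co-occurrence network for external graph tools
#'
#' Writes a node table (`id`, `phylum`, `degree`), an edge table (`source`,
#' `target`, `weight`, `sign`) as CSV, and a GraphML file loadable by Gephi
#' or Cytoscape.
#'
#' @param graph an [igraph::igraph] object as built by [build_network()].
#' @param prefix output path prefix; writes `<prefix>_nodes.csv`,
#'   `<prefix>_edges.csv` and `<prefix>.graphml`.
#' @return invisibly the three paths written.
#' @export
write_edge_list <- function(graph, prefix) {
  nodes <- data.frame(
    id = if (igraph::vcount(graph)) igraph::V(graph)$name else character(),
    phylum = if (igraph::vcount(graph))
      (igraph::vertex_attr(graph, "phylum") %||%
         rep("unknown", igraph::vcount(graph))) else character(),
    degree = if (igraph::vcount(graph)) igraph::degree(graph) else integer(),
    row.names = NULL)
  if (igraph::ecount(graph)) {
    ends <- igraph::as_edgelist(graph)
    edges <- data.frame(source = ends[, 1], target = ends[, 2],
                        weight = igraph::E(graph)$weight,
                        sign = igraph::E(graph)$sign)
  } else {
    edges <- data.frame(source = character(), target = character(),
                        weight = numeric(), sign = integer())
  }
  node_path <- paste0(prefix, "_nodes.csv")
  edge_path <- paste0(prefix, "_edges.csv")
  gml_path <- paste0(prefix, ".graphml")
  write.csv(nodes, node_path, row.names = FALSE, quote = FALSE)
  write.csv(edges, edge_path, row.names = FALSE, quote = FALSE)
  igraph::write_graph(graph, gml_path, format = "graphml")
  invisible(c(node_path, edge_path, gml_path))
}

#' Read an edge CSV back into a graph
#'
#' @param edge_path path to an edge CSV written by [write_edge_list()].
#' @return an undirected [igraph::igraph].
#' @export
read_edge_list <- function(edge_path) {
  edges <- read.csv(edge_path, stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(edges, directed = FALSE)
  g
}

#' Write a report table as TSV
#'
#' @param table a data.frame.
#' @param path output path.
#' @export
write_report_table <- function(table, path) {
  write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write / read a square distance-like matrix as TSV with labels
#'
#' @param m symmetric matrix with dimnames.
#' @param path file path.
#' @export
write_matrix_tsv <- function(m, path) {
  df <- data.frame(sample_id = rownames(m), as.data.frame(m, check.names = FALSE),
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  m
}
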