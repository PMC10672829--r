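# Rarefaction, alpha diversity (Chao1, Shannon) and Bray-Curtis.

#' Rarefy an OTU table to an even depth
#'
#' Subsamples every sample without replacement to exactly `depth` reads
#' (hypergeometric draw per sample). OTU columns that become all-zero are
#' retained so table dimensions stay stable; they are listed in the
#' `"zero_otus"` attribute.
#'
#' @param table an [otu_table()].
#' @param depth target reads per sample; must not exceed the smallest library.
#' @param seed integer seed.
#' @return a rarefied [otu_table()].
#' @export
rarefy <- function(table, depth, seed = NULL) {
  stopifnot(depth >= 1)
  tots <- rowSums(table)
  short <- rownames(table)[tots < depth]
  if (length(short))
    stop("depth ", depth, " exceeds the library size of sample(s): ",
         paste(short, collapse = ", "))
  if (!is.null(seed)) set.seed(seed)
  out <- vegan::rrarefy(unclass(table), depth)
  otu_table(out)
}

#' Bias-corrected Chao1 richness estimator
#'
#' `S_obs + F1 * (F1 - 1) / (2 * (F2 + 1))` where `F1`/`F2` are the numbers
#' of singleton and doubleton OTUs. The bias-corrected form stays finite when
#' there are no doubletons.
#'
#' @param counts non-negative integer vector.
#' @return estimated richness.
#' @export
chao1 <- function(counts) {
  if (any(counts < 0)) stop("negative counts")
  if (sum(counts) == 0) stop("Chao1 undefined for an all-zero sample")
  s_obs <- sum(counts > 0)
  f1 <- sum(counts == 1)
  f2 <- sum(counts == 2)
  s_obs + f1 * (f1 - 1) / (2 * (f2 + 1))
}

#' Shannon diversity
#'
#' `-sum(p_i * log(p_i, base))` over positive entries; natural log by
#' default.
#'
#' @param counts non-negative vector.
#' @param base logarithm base.
#' @return diversity value.
#' @export
shannon <- function(counts, base = exp(1)) {
  if (sum(counts) == 0) stop("Shannon undefined for an all-zero sample")
  as.numeric(vegan::diversity(counts, index = "shannon", base = base))
}

#' Bray-Curtis dissimilarity matrix
#'
#' `BC(u, v) = sum(|u_i - v_i|) / sum(u_i + v_i)`, computed on per-sample
#' relative abundances by default.
#'
#' @param table an [otu_table()] with at least 2 samples.
#' @param use_relative normalize each sample to relative abundances first.
#' @return symmetric matrix in \[0, 1\] with zero diagonal.
#' @export
bray_curtis <- function(table, use_relative = TRUE) {
  tab <- unclass(table)
  if (nrow(tab) < 2L) stop("need at least 2 samples")
  if (any(rowSums(tab) == 0)) stop("sample with zero total reads")
  x <- if (use_relative) tab / rowSums(tab) else tab
  as.matrix(vegan::vegdist(x, method = "bray"))
}

#' Rarefaction curve for one sample
#'
#' Mean observed richness over `reps` random subsamples at each depth.
#'
#' @param counts one sample's count vector.
#' @param depths increasing read depths, each at most `sum(counts)`.
#' @param reps subsamples per depth.
#' @param seed integer seed.
#' @return data.frame: depth, mean_richness.
#' @export
rarefaction_curve <- function(counts, depths, reps = 10, seed = NULL) {
  total <- sum(counts)
  if (any(depths > total)) stop("depth exceeds sample total ", total)
  if (any(depths < 1)) stop("depths must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  reads <- rep.int(seq_along(counts), counts)
  mean_rich <- vapply(depths, function(d) {
    mean(vapply(seq_len(reps), function(r)
      length(unique(sample(reads, d))), numeric(1)))
  }, numeric(1))
  data.frame(depth = depths, mean_richness = mean_rich)
}

#' Per-sample alpha-diversity report
#'
#' @param table an [otu_table()].
#' @return data.frame: sample_id, chao1, shannon, depth.
#' @export
alpha_diversity <- function(table) {
  tab <- unclass(table)
  data.frame(sample_id = rownames(tab),
             chao1 = apply(tab, 1, chao1),
             shannon = apply(tab, 1, shannon),
             depth = rowSums(tab),
             row.names = NULL)
}
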