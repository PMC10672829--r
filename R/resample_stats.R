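# Rank and permutation statistics used across the pipeline. Standard tests
# delegate to stats/vegan; every permutation test is seedable and reports
# (statistic, p_value, n_permutations, seed).

.test_result <- function(statistic, p_value, n_permutations = 0L, seed = NULL,
                         extra = list()) {
  structure(c(list(statistic = unname(statistic), p_value = unname(p_value),
                   n_permutations = n_permutations, seed = seed), extra),
            class = "test_result")
}

#' Spearman rank correlation test
#'
#' Average ranks for ties; p-value from the t approximation.
#'
#' @param x,y numeric vectors of equal length (>= 5).
#' @return a `test_result` list (statistic = rho, p_value).
#' @export
spearman <- function(x, y) {
  if (length(x) != length(y)) stop("x and y differ in length")
  if (length(x) < 5) stop("need at least 5 observations")
  if (sd(x) == 0 || sd(y) == 0) stop("Spearman undefined for a constant vector")
  ct <- suppressWarnings(cor.test(x, y, method = "spearman", exact = FALSE))
  .test_result(ct$estimate, ct$p.value)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p p-values in \[0, 1\].
#' @return adjusted p-values (monotone, capped at 1, elementwise >= input).
#' @export
bh_adjust <- function(p) {
  if (any(!is.na(p) & (p < 0 | p > 1))) stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

.as_dist_checked <- function(m) {
  if (inherits(m, "dist")) return(m)
  m <- as.matrix(m)
  diag(m) <- 0
  stats::as.dist(m)
}

#' Mantel test between two distance matrices
#'
#' Correlates the lower-triangle entries and permutes the rows/columns of one
#' matrix jointly for the null; Spearman correlation by default. p-value uses
#' the +1 correction: `(1 + #(perm >= obs)) / (1 + n_perm)`.
#'
#' @param d1,d2 distance matrices (`dist` or labelled square matrices) over
#'   the same samples in the same order.
#' @param n_perm number of permutations.
#' @param method `"spearman"` or `"pearson"`.
#' @param seed integer seed.
#' @return a `test_result` (statistic = r).
#' @export
mantel <- function(d1, d2, n_perm = 999, method = c("spearman", "pearson"),
                   seed = NULL) {
  method <- match.arg(method)
  m1 <- as.matrix(d1); m2 <- as.matrix(d2)
  if (!is.null(rownames(m1)) && !is.null(rownames(m2)) &&
      !identical(rownames(m1), rownames(m2)))
    stop("distance matrices carry different labels or orders")
  if (!is.null(seed)) set.seed(seed)
  fit <- vegan::mantel(.as_dist_checked(m1), .as_dist_checked(m2),
                       method = method, permutations = n_perm)
  .test_result(fit$statistic, fit$signif, n_perm, seed)
}

#' PERMANOVA (one factor)
#'
#' Pseudo-F from the among/within sum-of-squares decomposition of a distance
#' matrix, with a label-permutation p-value (via `vegan::adonis2`).
#'
#' @param d distance matrix over the samples.
#' @param groups factor with >= 2 levels, each with >= 2 members.
#' @param n_perm,seed permutation controls.
#' @return a `test_result` (statistic = pseudo-F, plus `r_squared`).
#' @export
permanova <- function(d, groups, n_perm = 999, seed = NULL) {
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need at least 2 groups")
  if (any(table(groups) < 2)) stop("singleton group(s): ",
    paste(names(which(table(groups) < 2)), collapse = ", "))
  if (!is.null(seed)) set.seed(seed)
  dd <- .as_dist_checked(d)
  fit <- vegan::adonis2(dd ~ groups, permutations = n_perm)
  .test_result(fit$F[1], fit$`Pr(>F)`[1], n_perm, seed,
               extra = list(r_squared = fit$R2[1]))
}

#' Kruskal-Wallis rank-sum test
#'
#' @param values numeric vector.
#' @param groups factor of the same length.
#' @return a `test_result` (statistic = H).
#' @export
kruskal_wallis <- function(values, groups) {
  groups <- factor(groups)
  if (any(table(groups) == 0) || nlevels(groups) < 2 || !length(values))
    stop("need at least 2 non-empty groups")
  fit <- kruskal.test(values, groups)
  .test_result(fit$statistic, fit$p.value)
}

#' Wilcoxon rank-sum (Mann-Whitney) test
#'
#' @param a,b numeric vectors.
#' @return a `test_result` (statistic = W).
#' @export
wilcoxon_rank_sum <- function(a, b) {
  if (!length(a) || !length(b)) stop("empty group")
  fit <- suppressWarnings(wilcox.test(a, b))
  .test_result(fit$statistic, fit$p.value)
}

#' Mantel correlations between betaNTI and environmental variables
#'
#' For each environmental variable, builds a Euclidean distance matrix on the
#' z-standardized values and Mantel-correlates it with the betaNTI matrix,
#' yielding a report shaped like a per-habitat variable/r/p table.
#'
#' @param bnti a `"beta_nti"` result or a labelled betaNTI matrix.
#' @param frame sample metadata carrying the variables.
#' @param variables covariate column names to test.
#' @param n_perm,method,seed Mantel controls (see [mantel()]).
#' @return data.frame: variable, r, p, n_permutations.
#' @export
mantel_env_table <- function(bnti, frame, variables, n_perm = 999,
                             method = "spearman", seed = NULL) {
  if (inherits(bnti, "beta_nti")) bnti <- bnti$bnti
  labs <- rownames(bnti)
  frame <- frame[match(labs, frame$sample_id), , drop = FALSE]
  if (anyNA(frame$sample_id)) stop("samples absent from metadata")
  seeds <- if (is.null(seed)) rep(list(NULL), length(variables)) else
    as.list(seed + seq_along(variables))
  rows <- lapply(seq_along(variables), function(k) {
    v <- variables[k]
    if (!v %in% names(frame)) stop("covariate absent from metadata: ", v)
    x <- frame[[v]]
    if (anyNA(x)) stop("covariate '", v, "' has missing values for these samples")
    d_env <- dist(scale(x))
    attr_lab <- labs
    m_env <- as.matrix(d_env)
    dimnames(m_env) <- list(attr_lab, attr_lab)
    fit <- mantel(bnti, m_env, n_perm = n_perm, method = method,
                  seed = seeds[[k]])
    data.frame(variable = v, r = fit$statistic, p = fit$p_value,
               n_permutations = n_perm)
  })
  do.call(rbind, rows)
}
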