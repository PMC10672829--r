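# MNTD / NTI / betaMNTD / betaNTI with tip-label randomization nulls.
#
# The null model shuffles taxon labels across the patristic distance matrix
# restricted to the taxa present in the community pool under analysis
# ("taxa.labels"-style). z-scores are (obs - null mean) / null sd; NTI is the
# negative of the per-sample z, betaNTI is the between-sample z itself.

.comm_index <- function(comm, labels) {
  if (!is.null(names(comm))) {
    miss <- setdiff(names(comm)[comm > 0], labels)
    if (length(miss))
      stop("taxa absent from distance matrix: ", paste(miss, collapse = ", "))
    x <- setNames(numeric(length(labels)), labels)
    x[names(comm)] <- comm
    comm <- x
  } else if (length(comm) != length(labels)) {
    stop("unnamed community vector must match the distance matrix dimension")
  }
  idx <- which(comm > 0)
  list(idx0 = idx - 1L, w = comm[idx] / sum(comm[idx]))
}

#' Mean nearest taxon distance (MNTD)
#'
#' Average patristic distance from each taxon present in a community to its
#' closest other taxon in the same community; with `weighted = TRUE` the
#' average is weighted by the focal taxa's relative abundances.
#'
#' @param comm abundance (or presence) vector; either named by taxa in `D` or
#'   aligned to `D`'s rows.
#' @param D symmetric patristic distance matrix (see [patristic_distances()]).
#' @param weighted abundance-weight the nearest-neighbour distances.
#' @return a single numeric value.
#' @export
mntd <- function(comm, D, weighted = FALSE) {
  ci <- .comm_index(comm, rownames(D))
  if (length(ci$idx0) < 2L) stop("MNTD needs at least 2 taxa present")
  cpp_mntd(D, ci$idx0, ci$w, weighted, seq_len(nrow(D)) - 1L)
}

#' Standardized effect size of MNTD and the nearest taxon index (NTI)
#'
#' Compares the observed MNTD with a null distribution obtained by shuffling
#' taxon labels on the distance matrix `n_null` times. NTI is the negative
#' z-score; positive NTI means phylogenetic clustering. When every shuffle
#' leaves MNTD unchanged (e.g. a star phylogeny, or the community spans the
#' whole pool) the null sd is 0: the result is flagged `degenerate` and z is
#' reported as 0 with a warning.
#'
#' @inheritParams mntd
#' @param n_null number of label randomizations.
#' @param seed integer seed for the shuffles.
#' @return list with `observed`, `null_mean`, `null_sd`, `z`, `nti`,
#'   `degenerate`, `n_null`, `seed`.
#' @export
ses_mntd <- function(comm, D, weighted = FALSE, n_null = 999, seed = NULL) {
  stopifnot(n_null >= 1)
  ci <- .comm_index(comm, rownames(D))
  if (length(ci$idx0) < 2L) stop("MNTD needs at least 2 taxa present")
  n <- nrow(D)
  ident <- seq_len(n) - 1L
  obs <- cpp_mntd(D, ci$idx0, ci$w, weighted, ident)
  if (!is.null(seed)) set.seed(seed)
  nulls <- vapply(seq_len(n_null), function(b)
    cpp_mntd(D, ci$idx0, ci$w, weighted, sample.int(n) - 1L), numeric(1))
  null_mean <- mean(nulls)
  null_sd <- sd(nulls)
  degenerate <- !is.finite(null_sd) || null_sd < 1e-12
  if (degenerate) {
    warning("degenerate null distribution (sd = 0); z reported as 0")
    z <- 0
  } else {
    z <- (obs - null_mean) / null_sd
  }
  structure(list(observed = obs, null_mean = null_mean, null_sd = null_sd,
                 z = z, nti = -z, degenerate = degenerate,
                 n_null = n_null, seed = seed),
            class = "ses_result")
}

#' Per-sample NTI table
#'
#' Runs [ses_mntd()] for every sample of an OTU table against one shared
#' taxon pool (all OTUs present anywhere in the table), the pool the label
#' shuffles randomize over.
#'
#' @param table an [otu_table()].
#' @param tree phylogeny covering the table's OTUs (alternative to `D`).
#' @param D precomputed patristic distance matrix (alternative to `tree`).
#' @param weighted abundance-weight MNTD (default `FALSE` for NTI).
#' @param n_null,seed null-model controls.
#' @return data.frame: sample_id, mntd_obs, null_mean, null_sd, nti,
#'   degenerate_flag.
#' @export
nti_table <- function(table, tree = NULL, D = NULL, weighted = FALSE,
                      n_null = 999, seed = NULL) {
  D <- .pool_distances(table, tree, D)
  if (!is.null(seed)) set.seed(seed)
  rows <- lapply(rownames(table), function(s) {
    comm <- setNames(as.numeric(table[s, colnames(D)]), colnames(D))
    r <- suppressWarnings(ses_mntd(comm, D, weighted = weighted,
                                   n_null = n_null, seed = NULL))
    data.frame(sample_id = s, mntd_obs = r$observed, null_mean = r$null_mean,
               null_sd = r$null_sd, nti = r$nti,
               degenerate_flag = r$degenerate)
  })
  do.call(rbind, rows)
}

# restrict D to OTUs occurring in the table (the shuffle pool)
.pool_distances <- function(table, tree, D) {
  pool <- colnames(table)[colSums(table) > 0L]
  if (is.null(D)) {
    if (is.null(tree)) stop("supply either a tree or a distance matrix")
    D <- patristic_distances(tree, pool)
  } else {
    miss <- setdiff(pool, rownames(D))
    if (length(miss))
      stop("OTUs absent from distance matrix: ", paste(miss, collapse = ", "))
    D <- D[pool, pool, drop = FALSE]
  }
  D
}

#' Between-community mean nearest taxon distance (betaMNTD)
#'
#' Mean distance from each taxon in one community to its nearest taxon in the
#' other, averaged symmetrically over both directions; abundance-weighted by
#' default, as in the turnover form of the metric.
#'
#' @param comm_a,comm_b abundance vectors (named by taxa in `D` or aligned to
#'   it).
#' @inheritParams mntd
#' @return a single numeric value.
#' @export
beta_mntd <- function(comm_a, comm_b, D, weighted = TRUE) {
  a <- .comm_index(comm_a, rownames(D))
  b <- .comm_index(comm_b, rownames(D))
  if (!length(a$idx0) || !length(b$idx0)) stop("empty community")
  cpp_beta_mntd_pair(D, a$idx0, a$w, b$idx0, b$w, weighted,
                     seq_len(nrow(D)) - 1L)
}

#' Beta nearest taxon index (betaNTI) for all sample pairs
#'
#' For each pair of samples the observed betaMNTD is compared with `n_null`
#' label shuffles of the distance matrix restricted to the pooled taxon set;
#' one shared shuffle sequence serves every pair, so the matrix is symmetric
#' by construction. |betaNTI| > 2 indicates deterministic turnover
#' (selection); values in between indicate stochastic assembly.
#'
#' @inheritParams nti_table
#' @param weighted abundance-weight betaMNTD (default `TRUE`).
#' @return list of class `"beta_nti"` with `bnti` (symmetric matrix, NA
#'   diagonal), `bmntd` (observed), `null_mean`, `null_sd`, `degenerate`
#'   (logical matrix), `n_null`, `seed`.
#' @export
beta_nti <- function(table, tree = NULL, D = NULL, weighted = TRUE,
                     n_null = 999, seed = NULL) {
  stopifnot(n_null >= 1)
  D <- .pool_distances(table, tree, D)
  n <- nrow(D)
  tab <- unclass(table)[, rownames(D), drop = FALSE]
  idx <- lapply(seq_len(nrow(tab)), function(i) which(tab[i, ] > 0) - 1L)
  w <- lapply(seq_len(nrow(tab)), function(i) {
    x <- tab[i, tab[i, ] > 0]
    x / sum(x)
  })
  ident <- seq_len(n) - 1L
  obs <- cpp_beta_mntd_all(D, idx, w, weighted, ident)
  if (!is.null(seed)) set.seed(seed)
  s1 <- matrix(0, nrow(tab), nrow(tab))
  s2 <- matrix(0, nrow(tab), nrow(tab))
  for (b in seq_len(n_null)) {
    nm <- cpp_beta_mntd_all(D, idx, w, weighted, sample.int(n) - 1L)
    s1 <- s1 + nm
    s2 <- s2 + nm * nm
  }
  null_mean <- s1 / n_null
  null_var <- (s2 - n_null * null_mean^2) / max(n_null - 1L, 1L)
  null_sd <- sqrt(pmax(null_var, 0))
  degenerate <- null_sd < 1e-12
  bnti <- (obs - null_mean) / null_sd
  bnti[degenerate] <- 0
  diag(bnti) <- NA_real_
  labs <- rownames(table)
  dimnames(bnti) <- dimnames(obs) <- dimnames(null_mean) <-
    dimnames(null_sd) <- dimnames(degenerate) <- list(labs, labs)
  structure(list(bnti = bnti, bmntd = obs, null_mean = null_mean,
                 null_sd = null_sd, degenerate = degenerate,
                 n_null = n_null, seed = seed),
            class = "beta_nti")
}
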