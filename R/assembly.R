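# Bray-Curtis-based Raup-Crick null model and the five-process framework:
# betaNTI separates selection (|betaNTI| > 2) from stochastic turnover, and
# RCbray splits the stochastic fraction into dispersal limitation
# (RCbray > +0.95), homogenizing dispersal (RCbray < -0.95) and drift
# (|RCbray| <= 0.95). All thresholds are strict inequalities.

.process_levels <- c("variable_selection", "homogeneous_selection",
                     "dispersal_limitation", "homogenizing_dispersal",
                     "drift")

# one null community: membership by occurrence frequency, one individual per
# member, remaining reads multinomial with probability proportional to the
# pool-wide relative abundance of the chosen taxa
.null_community <- function(richness, total, occ, gamma) {
  n_pool <- length(occ)
  memb <- sample.int(n_pool, richness, prob = occ, replace = FALSE)
  x <- rep(1, richness)
  if (total > richness)
    x <- x + drop(rmultinom(1L, total - richness, gamma[memb]))
  list(memb = memb, x = x)
}

.bc_sparse <- function(m1, x1, m2, x2) {
  all_m <- c(m1, m2)
  u <- c(x1, numeric(length(m2)))
  v <- c(numeric(length(m1)), x2)
  o <- order(all_m)
  all_m <- all_m[o]; u <- u[o]; v <- v[o]
  dup <- c(FALSE, all_m[-1] == all_m[-length(all_m)])
  grp <- cumsum(!dup)
  uu <- rowsum(u, grp); vv <- rowsum(v, grp)
  sum(abs(uu - vv)) / sum(uu + vv)
}

#' Bray-Curtis-based Raup-Crick (RCbray) for all sample pairs
#'
#' For each pair of samples, `n_null` pairs of null communities are assembled
#' preserving each sample's observed richness and total read count: taxon
#' membership is drawn (without replacement) with probability proportional to
#' occurrence frequency across the table, and reads are allocated with
#' probability proportional to pool-wide relative abundance. RCbray is the
#' tie-corrected fraction of null Bray-Curtis values below the observed one,
#' rescaled to \[-1, +1\]:
#' `RC = 2 * (#(null < obs) + 0.5 * #(null = obs)) / n_null - 1`.
#'
#' @param table an [otu_table()] of counts (not relative abundances).
#' @param n_null null pairs per sample pair.
#' @param seed master seed; each pair gets its own derived seed so results
#'   do not depend on pair evaluation order.
#' @return list of class `"rcbray"` with `rc` (symmetric matrix in
#'   \[-1, 1\], NA diagonal), `n_null`, `seed`.
#' @export
raup_crick_bray <- function(table, n_null = 999, seed = NULL) {
  tab <- unclass(table)
  if (nrow(tab) < 2L) stop("need at least 2 samples")
  if (any(rowSums(tab) == 0)) stop("sample with zero total reads")
  # canonical sample/OTU order makes the result exactly invariant to
  # permutations of the input table
  orig_order <- rownames(tab)
  tab <- tab[order(rownames(tab)), order(colnames(tab)), drop = FALSE]
  pool <- colSums(tab) > 0
  tab <- tab[, pool, drop = FALSE]
  occ <- colMeans(tab > 0)
  gamma <- colSums(tab) / sum(tab)
  n <- nrow(tab)
  rich <- rowSums(tab > 0)
  tot <- rowSums(tab)
  memb_obs <- lapply(seq_len(n), function(i) which(tab[i, ] > 0))
  x_obs <- lapply(seq_len(n), function(i) tab[i, tab[i, ] > 0])
  if (!is.null(seed)) set.seed(seed)
  pair_seeds <- sample.int(.Machine$integer.max - 1L, n * (n - 1L) / 2L)
  rc <- matrix(NA_real_, n, n, dimnames = list(rownames(tab), rownames(tab)))
  k <- 0L
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      k <- k + 1L
      set.seed(pair_seeds[k])
      obs <- .bc_sparse(memb_obs[[i]], x_obs[[i]], memb_obs[[j]], x_obs[[j]])
      less <- 0; ties <- 0
      for (b in seq_len(n_null)) {
        a1 <- .null_community(rich[i], tot[i], occ, gamma)
        a2 <- .null_community(rich[j], tot[j], occ, gamma)
        nb <- .bc_sparse(a1$memb, a1$x, a2$memb, a2$x)
        if (nb < obs - 1e-12) less <- less + 1
        else if (abs(nb - obs) <= 1e-12) ties <- ties + 1
      }
      rc[i, j] <- rc[j, i] <- 2 * (less + 0.5 * ties) / n_null - 1
    }
  }
  rc <- rc[orig_order, orig_order]
  structure(list(rc = rc, n_null = n_null, seed = seed), class = "rcbray")
}

#' Classify a sample pair into one of the five assembly processes
#'
#' Applies the threshold rules in order: betaNTI > +2 is variable
#' (heterogeneous) selection; betaNTI < -2 is homogeneous selection;
#' otherwise RCbray > +0.95 is dispersal limitation, RCbray < -0.95 is
#' homogenizing dispersal, and the remainder (|RCbray| <= 0.95) is drift
#' (undominated). All inequalities are strict: a value exactly at a threshold
#' falls through to the next rule. `NA` inputs give an `NA` label.
#'
#' @param bnti,rc numeric vectors (recycled to common length).
#' @return factor with levels variable_selection, homogeneous_selection,
#'   dispersal_limitation, homogenizing_dispersal, drift.
#' @export
classify_pair <- function(bnti, rc) {
  n <- max(length(bnti), length(rc))
  bnti <- rep_len(bnti, n)
  rc <- rep_len(rc, n)
  out <- rep(NA_character_, n)
  ok <- is.finite(bnti) & is.finite(rc)
  out[ok & bnti > 2] <- "variable_selection"
  out[ok & bnti < -2] <- "homogeneous_selection"
  stoch <- ok & is.na(out)
  out[stoch & rc > 0.95] <- "dispersal_limitation"
  out[stoch & rc < -0.95] <- "homogenizing_dispersal"
  out[stoch & is.na(out)] <- "drift"
  factor(out, levels = .process_levels)
}

#' Partition assembly processes by sample group
#'
#' Crosses the betaNTI and RCbray matrices with the classification rules of
#' [classify_pair()] over all within-group sample pairs and reports the
#' proportion of pairs assigned to each process, the stochastic fraction
#' (dispersal limitation + homogenizing dispersal + drift), and the pooled
#' betaNTI distribution per group.
#'
#' @param bnti a `"beta_nti"` result or its matrix.
#' @param rc an `"rcbray"` result or its matrix.
#' @param frame sample metadata (see [read_sample_frame()]).
#' @param grouping metadata column names defining the groups; use
#'   `character(0)` for a single pooled group.
#' @return list of class `"process_partition"`: `proportions` (long
#'   data.frame group/process/proportion/n_pairs), `summary` (per-group
#'   n_pairs, n_excluded, stochastic_fraction, deterministic_fraction) and
#'   `bnti_values` (long data.frame of within-group betaNTI values).
#' @export
partition_processes <- function(bnti, rc, frame,
                                grouping = c("habitat", "treatment", "season")) {
  if (inherits(bnti, "beta_nti")) bnti <- bnti$bnti
  if (inherits(rc, "rcbray")) rc <- rc$rc
  labs <- rownames(bnti)
  if (!identical(sort(labs), sort(rownames(rc))))
    stop("betaNTI and RCbray matrices carry different sample labels")
  rc <- rc[labs, labs]
  miss <- setdiff(grouping, names(frame))
  if (length(miss)) stop("grouping column(s) absent from metadata: ",
                         paste(miss, collapse = ", "))
  frame <- frame[match(labs, frame$sample_id), , drop = FALSE]
  if (anyNA(frame$sample_id))
    stop("samples absent from metadata: ",
         paste(setdiff(labs, frame$sample_id), collapse = ", "))
  grp <- if (length(grouping)) {
    interaction(frame[grouping], sep = ".", drop = TRUE)
  } else {
    factor(rep("all", length(labs)))
  }
  props <- list(); summ <- list(); bvals <- list()
  for (g in levels(grp)) {
    members <- which(grp == g)
    if (length(members) < 2L) {
      warning("group '", g, "' has fewer than 2 samples; skipped")
      next
    }
    prs <- combn(members, 2L)
    b <- bnti[cbind(prs[1, ], prs[2, ])]
    r <- rc[cbind(prs[1, ], prs[2, ])]
    lab <- classify_pair(b, r)
    n_excluded <- sum(is.na(lab))
    n_pairs <- sum(!is.na(lab))
    if (n_pairs == 0L) next
    p <- as.numeric(table(lab)) / n_pairs
    props[[g]] <- data.frame(group = g, process = .process_levels,
                             proportion = p, n_pairs = n_pairs)
    stoch <- sum(p[match(c("dispersal_limitation", "homogenizing_dispersal",
                           "drift"), .process_levels)])
    summ[[g]] <- data.frame(group = g, n_pairs = n_pairs,
                            n_excluded = n_excluded,
                            stochastic_fraction = stoch,
                            deterministic_fraction = 1 - stoch)
    bvals[[g]] <- data.frame(group = g, bnti = b)
  }
  if (!length(props)) { # every group skipped: zero-row frames, same columns
    props <- list(data.frame(group = character(), process = character(),
                             proportion = numeric(), n_pairs = integer()))
    summ <- list(data.frame(group = character(), n_pairs = integer(),
                            n_excluded = integer(),
                            stochastic_fraction = numeric(),
                            deterministic_fraction = numeric()))
    bvals <- list(data.frame(group = character(), bnti = numeric()))
  }
  structure(list(proportions = do.call(rbind, c(props, make.row.names = FALSE)),
                 summary = do.call(rbind, c(summ, make.row.names = FALSE)),
                 bnti_values = do.call(rbind, c(bvals, make.row.names = FALSE)),
                 grouping = grouping),
            class = "process_partition")
}
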