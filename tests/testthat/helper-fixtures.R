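# Shared fixtures built in code: small trees with hand-checkable distances
# and independent brute-force oracles used across test files.

# caterpillar tree on 5 tips; every pairwise distance checkable by path sums
caterpillar_tree <- function() {
  ape::read.tree(text = "((((A:1,B:2):1,C:3):1,D:4):1,E:5):0;")
}

star_tree <- function(n = 4, len = 1) {
  tips <- paste(LETTERS[seq_len(n)], collapse = sprintf(":%g,", len))
  ape::read.tree(text = sprintf("(%s:%g):0;", tips, len))
}

# independent patristic oracle: sum edge lengths along ape::nodepath
brute_patristic <- function(tree) {
  n <- ape::Ntip(tree)
  D <- matrix(0, n, n, dimnames = list(tree$tip.label, tree$tip.label))
  edge_len <- function(a, b) {
    hit <- (tree$edge[, 1] == a & tree$edge[, 2] == b) |
      (tree$edge[, 1] == b & tree$edge[, 2] == a)
    tree$edge.length[hit]
  }
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      path <- ape::nodepath(tree, i, j)
      d <- sum(vapply(seq_len(length(path) - 1), function(k)
        edge_len(path[k], path[k + 1]), numeric(1)))
      D[i, j] <- D[j, i] <- d
    }
  }
  D
}

# brute-force nearest-neighbour MNTD oracle
brute_mntd <- function(comm, D, weighted = FALSE) {
  idx <- which(comm > 0)
  nn <- vapply(idx, function(i) min(D[i, setdiff(idx, i)]), numeric(1))
  if (weighted) sum(comm[idx] / sum(comm[idx]) * nn) else mean(nn)
}

# brute-force betaMNTD oracle
brute_beta_mntd <- function(a, b, D, weighted = TRUE) {
  ia <- which(a > 0); ib <- which(b > 0)
  nn_ab <- vapply(ia, function(i) min(D[i, ib]), numeric(1))
  nn_ba <- vapply(ib, function(i) min(D[i, ia]), numeric(1))
  if (weighted) {
    wa <- a[ia] / sum(a[ia]); wb <- b[ib] / sum(b[ib])
    0.5 * (sum(wa * nn_ab) + sum(wb * nn_ba))
  } else {
    0.5 * (mean(nn_ab) + mean(nn_ba))
  }
}

# small iid multinomial table from a lognormal pool
iid_table <- function(n_samples, n_otus, lib, seed) {
  tree <- simulate_tree(n_otus, seed = seed)
  spec <- regime_spec("drift", n_samples = n_samples, n_otus = n_otus,
                      library_size = lib, generations = 0, seed = seed + 1)
  list(tree = tree, table = simulate_regime(spec, tree))
}

# all permutations of 1..n (Heap's algorithm), for exhaustive null oracles
all_perms <- function(n) {
  out <- list()
  a <- seq_len(n)
  rec <- function(k) {
    if (k == 1L) {
      out[[length(out) + 1L]] <<- a
      return(invisible())
    }
    for (i in seq_len(k)) {
      rec(k - 1L)
      j <- if (k %% 2L == 0L) i else 1L
      tmp <- a[j]; a[j] <<- a[k]; a[k] <<- tmp
    }
  }
  rec(n)
  out
}

# brute-force global transitivity and mean local clustering from an adjacency
# matrix: triangles and connected triples counted by direct triple enumeration
brute_transitivity <- function(adj) {
  n <- nrow(adj)
  tri <- 0; triples <- 0
  for (i in seq_len(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
    e <- adj[i, j] + adj[i, k] + adj[j, k]
    if (e == 3) tri <- tri + 1
  }
  deg <- rowSums(adj)
  triples <- sum(choose(deg, 2))
  local <- vapply(seq_len(n), function(i) {
    nb <- which(adj[i, ] > 0)
    if (length(nb) < 2) return(0)
    sub <- adj[nb, nb, drop = FALSE]
    sum(sub) / 2 / choose(length(nb), 2)
  }, numeric(1))
  list(global = if (triples > 0) 3 * tri / triples else NaN,
       mean_local = mean(local))
}

# all set partitions of 1..n as membership vectors (restricted growth strings)
all_set_partitions <- function(n) {
  out <- list()
  rec <- function(memb, next_block) {
    k <- length(memb) + 1L
    if (k > n) {
      out[[length(out) + 1L]] <<- memb
      return(invisible())
    }
    for (b in seq_len(next_block)) {
      rec(c(memb, b), max(next_block, b + 1L))
    }
  }
  rec(integer(), 1L)
  out
}

# Newman modularity of a membership vector on an unweighted adjacency matrix
brute_modularity <- function(adj, memb) {
  m2 <- sum(adj) # 2m
  deg <- rowSums(adj)
  same <- outer(memb, memb, "==")
  sum((adj - outer(deg, deg) / m2) * same) / m2
}
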