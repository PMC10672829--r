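test_that("the abundance filter keeps exactly the OTUs above threshold", {
  m <- matrix(c(960L, 20L, 10L, 10L,
                960L, 20L, 10L, 10L), 2, byrow = TRUE,
              dimnames = list(c("s1", "s2"), c("big", "mid", "low", "low2")))
  tab <- otu_table(m)
  # total reads 2000: big = 0.96, mid = 0.02, low = 0.01 each
  f1 <- suppressMessages(filter_otus(tab, threshold = 0.015))
  expect_equal(colnames(f1), c("big", "mid"))
  # threshold is strict: exactly 0.01 is dropped at threshold 0.01
  f2 <- suppressMessages(filter_otus(tab, threshold = 0.01))
  expect_equal(colnames(f2), c("big", "mid"))
  f3 <- suppressMessages(filter_otus(tab, threshold = 0.005))
  expect_equal(ncol(f3), 4L)
  expect_error(suppressMessages(filter_otus(tab, threshold = 0.99)),
               "no OTU")
})

test_that("correlation edges match pairwise cor.test and respect thresholds", {
  set.seed(3)
  n <- 12
  base <- rnorm(n)
  x <- cbind(a = base + rnorm(n, 0, 0.1),
             b = base + rnorm(n, 0, 0.1),
             c = -base + rnorm(n, 0, 0.1),
             d = rnorm(n))
  counts <- apply(x, 2, function(v) as.integer(100 + 20 * scale(v)))
  rownames(counts) <- sprintf("s%02d", 1:n)
  tab <- otu_table(counts)
  edges <- correlation_edges(tab, r_threshold = 0.6, alpha = 0.05,
                             use_relative = FALSE)
  key <- paste(edges$otu_a, edges$otu_b)
  expect_true(all(c("a b", "a c", "b c") %in% key))
  expect_false(any(grepl("d", key)))
  expect_equal(attr(edges, "n_tested"), choose(4, 2))

  # r and p agree with cor.test on the raw columns
  i <- which(edges$otu_a == "a" & edges$otu_b == "b")
  ct <- suppressWarnings(cor.test(counts[, "a"], counts[, "b"],
                                  method = "spearman", exact = FALSE))
  expect_equal(edges$r[i], unname(ct$estimate))
  expect_equal(edges$p[i], ct$p.value)
  # q is the BH adjustment over all tested pairs
  rall <- suppressWarnings(cor(counts, method = "spearman"))
  ut <- rall[upper.tri(rall)]
  tt <- ut * sqrt((n - 2) / (1 - ut^2))
  qall <- bh_adjust(2 * pt(-abs(tt), n - 2))
  expect_true(all(edges$q %in% qall))
  expect_equal(edges$sign, ifelse(edges$r > 0, 1L, -1L))

  # constant OTUs are excluded, not propagated as NA
  counts2 <- cbind(counts, flat = 50L)
  e2 <- correlation_edges(otu_table(counts2), use_relative = FALSE)
  expect_equal(attr(e2, "n_constant_excluded"), 4L)
  expect_error(correlation_edges(otu_table(counts[1:3, ])), "at least 5")
})

test_that("network assembly produces a simple annotated graph", {
  edges <- data.frame(otu_a = c("A", "A", "B"), otu_b = c("B", "B", "C"),
                      r = c(0.9, 0.9, -0.7), p = 0.001, q = 0.002,
                      sign = c(1L, 1L, -1L))
  tab <- otu_table(matrix(c(10L, 30L, 60L,
                            20L, 30L, 50L), 2, byrow = TRUE,
                          dimnames = list(c("s1", "s2"), c("A", "B", "C"))))
  g <- build_network(edges, table = tab, phylum = c(A = "Proteobacteria"))
  expect_equal(igraph::ecount(g), 2L) # duplicate A-B collapsed
  expect_setequal(igraph::V(g)$name, c("A", "B", "C"))
  expect_equal(igraph::V(g)$phylum[igraph::V(g)$name == "A"],
               "Proteobacteria")
  expect_equal(igraph::V(g)$phylum[igraph::V(g)$name == "B"], "unknown")
  a_rel <- mean(c(10 / 100, 20 / 100))
  expect_equal(igraph::V(g)$mean_rel_abund[igraph::V(g)$name == "A"], a_rel)
  expect_equal(igraph::vcount(build_network(edges[0, ])), 0L)
})

test_that("topology metrics match closed forms on known graphs", {
  # triangle: every metric known exactly
  tri <- data.frame(otu_a = c("A", "B", "C"), otu_b = c("B", "C", "A"),
                    r = c(0.9, 0.8, -0.7), p = 0.001, q = 0.002,
                    sign = c(1L, 1L, -1L))
  t1 <- topology(build_network(tri))
  expect_equal(t1$nodes, 3L)
  expect_equal(t1$edges, 3L)
  expect_equal(t1$average_degree, 2)
  expect_equal(t1$average_transitivity, 1)
  expect_equal(t1$average_clustering_coefficient, 1)
  expect_equal(t1$average_path_length, 1)
  expect_equal(t1$diameter, 1)
  expect_equal(t1$graph_density, 1)
  expect_equal(t1$positive_relationship_pct, 100 * 2 / 3)
  expect_false(t1$on_largest_component)

  # path A-B-C: no triangles, known path metrics
  path <- data.frame(otu_a = c("A", "B"), otu_b = c("B", "C"),
                     r = c(0.9, 0.8), p = 0.001, q = 0.002, sign = 1L)
  t2 <- topology(build_network(path))
  expect_equal(t2$average_transitivity, 0)
  expect_equal(t2$average_clustering_coefficient, 0)
  expect_equal(t2$average_path_length, (1 + 1 + 2) / 3)
  expect_equal(t2$diameter, 2)
  expect_equal(t2$graph_density, 2 / 3)

  # two components: path metrics computed on the giant one and flagged
  two <- rbind(path, data.frame(otu_a = "X", otu_b = "Y", r = 0.9, p = 0.001,
                                q = 0.002, sign = 1L))
  t3 <- topology(build_network(two))
  expect_true(t3$on_largest_component)
  expect_equal(t3$diameter, 2)

  # empty graph: counts zero, metrics NA
  t0 <- topology(build_network(path[0, ]))
  expect_equal(t0$nodes, 0L)
  expect_true(is.na(t0$average_path_length))
})

test_that("modularity of the greedy partition matches igraph on two cliques", {
  clique <- function(members) {
    prs <- t(combn(members, 2))
    data.frame(otu_a = prs[, 1], otu_b = prs[, 2], r = 0.9, p = 0.001,
               q = 0.002, sign = 1L)
  }
  edges <- rbind(clique(paste0("L", 1:4)), clique(paste0("R", 1:4)),
                 data.frame(otu_a = "L1", otu_b = "R1", r = 0.7, p = 0.001,
                            q = 0.002, sign = 1L))
  g <- build_network(edges)
  t1 <- topology(g)
  # the natural partition is the two cliques; compute its modularity directly
  memb <- ifelse(grepl("^L", igraph::V(g)$name), 1L, 2L)
  gu <- igraph::delete_edge_attr(g, "weight")
  expect_equal(t1$modularity, igraph::modularity(gu, memb))
  expect_gt(t1$modularity, 0.3)
})

test_that("keystone selection returns the top-degree nodes", {
  star <- data.frame(otu_a = "hub", otu_b = paste0("leaf", 1:6), r = 0.9,
                     p = 0.001, q = 0.002, sign = 1L)
  g <- build_network(star)
  expect_equal(keystone_nodes(g, top_frac = 0.01), "hub")
  expect_equal(length(keystone_nodes(g, top_frac = 0.5)), 4L)
  expect_equal(keystone_nodes(build_network(star[0, ])), character())
})
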