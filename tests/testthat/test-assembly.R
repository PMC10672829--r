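test_that("RCbray matrices are bounded, symmetric, and reproducible", {
  tab <- iid_table(8, 60, 400, seed = 17)$table
  r1 <- raup_crick_bray(tab, n_null = 99, seed = 5)
  r2 <- raup_crick_bray(tab, n_null = 99, seed = 5)
  expect_identical(r1$rc, r2$rc)
  expect_true(isSymmetric(r1$rc))
  expect_true(all(is.na(diag(r1$rc))))
  off <- r1$rc[upper.tri(r1$rc)]
  expect_true(all(off >= -1 & off <= 1))
  expect_equal(rownames(r1$rc), rownames(tab))
})

test_that("RCbray is exactly invariant to sample and OTU permutations", {
  tab <- iid_table(6, 40, 300, seed = 23)$table
  base <- raup_crick_bray(tab, n_null = 49, seed = 9)$rc
  perm <- unclass(tab)[sample(nrow(tab)), sample(ncol(tab))]
  shuffled <- raup_crick_bray(otu_table(perm), n_null = 49, seed = 9)$rc
  expect_equal(shuffled[rownames(base), rownames(base)], base)
})

test_that("RCbray separates identical from disjoint community pairs", {
  # two copies of one community vs two disjoint communities over a shared
  # pool: identical pairs sit far below the null (RC near -1), disjoint
  # pairs far above it (RC near +1)
  set.seed(31)
  pool <- 40
  a <- rmultinom(1, 500, rep(1 / pool, pool))[, 1]
  ids <- sprintf("OTU_%02d", 1:pool)
  same <- matrix(rep(a, 2), 2, byrow = TRUE,
                 dimnames = list(c("x", "y"), ids))
  # a third distinct sample keeps occupancy frequencies non-degenerate
  b <- rmultinom(1, 500, rep(1 / pool, pool))[, 1]
  same <- rbind(same, z = b)
  rc_same <- raup_crick_bray(otu_table(same + 0L), n_null = 199, seed = 2)
  expect_lt(rc_same$rc["x", "y"], -0.9)

  left <- right <- setNames(integer(pool), ids)
  left[1:12] <- 40L; right[29:40] <- 40L
  mid <- setNames(integer(pool), ids); mid[13:28] <- 30L
  disj <- rbind(L = left, R = right, M = mid)
  rc_disj <- raup_crick_bray(otu_table(disj), n_null = 199, seed = 2)
  expect_gt(rc_disj$rc["L", "R"], 0.9)
})

test_that("pair classification follows the strict threshold rules", {
  expect_equal(as.character(classify_pair(2.5, 0)), "variable_selection")
  expect_equal(as.character(classify_pair(-2.5, 0)), "homogeneous_selection")
  expect_equal(as.character(classify_pair(0, 0.99)), "dispersal_limitation")
  expect_equal(as.character(classify_pair(0, -0.99)), "homogenizing_dispersal")
  expect_equal(as.character(classify_pair(0, 0)), "drift")
  # selection takes precedence over any RC value
  expect_equal(as.character(classify_pair(3, 0.99)), "variable_selection")
  expect_equal(as.character(classify_pair(-3, -0.99)), "homogeneous_selection")
  # NA propagates
  expect_true(is.na(classify_pair(NA, 0)))
  expect_true(is.na(classify_pair(0, NA)))
  # vectorized with recycling
  v <- classify_pair(c(3, -3, 0, 0, 0), c(0, 0, 0.96, -0.96, 0.5))
  expect_equal(as.character(v),
               c("variable_selection", "homogeneous_selection",
                 "dispersal_limitation", "homogenizing_dispersal", "drift"))
  expect_equal(levels(v), c("variable_selection", "homogeneous_selection",
                            "dispersal_limitation", "homogenizing_dispersal",
                            "drift"))
})

test_that("process partitioning sums to one within each group", {
  n <- 10
  labs <- sprintf("s%02d", 1:n)
  set.seed(41)
  bnti <- matrix(rnorm(n * n, 0, 2), n, n, dimnames = list(labs, labs))
  bnti[lower.tri(bnti)] <- t(bnti)[lower.tri(bnti)]
  diag(bnti) <- NA
  rc <- matrix(runif(n * n, -1, 1), n, n, dimnames = list(labs, labs))
  rc[lower.tri(rc)] <- t(rc)[lower.tri(rc)]
  diag(rc) <- NA
  frame <- data.frame(sample_id = labs,
                      habitat = rep(c("water", "sediment"), each = 5),
                      treatment = "C", season = "spring", tank = 1:n)
  part <- partition_processes(bnti, rc, frame, grouping = "habitat")
  agg <- tapply(part$proportions$proportion, part$proportions$group, sum)
  expect_equal(as.numeric(agg), rep(1, 2))
  expect_equal(sort(unique(part$proportions$group)),
               c("sediment", "water"))
  expect_equal(part$summary$n_pairs, rep(choose(5, 2), 2))
  expect_equal(part$summary$stochastic_fraction +
                 part$summary$deterministic_fraction, rep(1, 2))

  # hand-check one group against direct classification of its pairs
  w <- labs[frame$habitat == "water"]
  prs <- combn(w, 2)
  lab <- classify_pair(bnti[cbind(prs[1, ], prs[2, ])],
                       rc[cbind(prs[1, ], prs[2, ])])
  pw <- part$proportions[part$proportions$group == "water", ]
  expect_equal(pw$proportion,
               as.numeric(table(lab)) / length(lab))

  # pooled grouping and small-group warning
  pooled <- partition_processes(bnti, rc, frame, grouping = character(0))
  expect_equal(pooled$summary$n_pairs, choose(n, 2))
  frame$habitat[1:5] <- c("water", rep("sediment", 4))
  expect_warning(partition_processes(bnti, rc, frame, grouping = "habitat"),
                 "fewer than 2")
})

test_that("partitioning rejects mismatched inputs", {
  labs <- c("a", "b", "c")
  m <- matrix(0, 3, 3, dimnames = list(labs, labs))
  frame <- data.frame(sample_id = labs, habitat = "water", treatment = "C",
                      season = "spring", tank = 1)
  m2 <- m
  rownames(m2) <- colnames(m2) <- c("a", "b", "zzz")
  expect_error(partition_processes(m, m2, frame), "different sample labels")
  expect_error(partition_processes(m, m, frame, grouping = "nope"), "nope")
  expect_error(partition_processes(m, m, frame[1:2, ]), "absent")
})
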