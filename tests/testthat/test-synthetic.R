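test_that("Yule tree simulation is deterministic and well-formed", {
  t1 <- simulate_tree(100, seed = 7)
  t2 <- simulate_tree(100, seed = 7)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))
  expect_equal(ape::Ntip(t1), 100L)
  expect_equal(t1$Nnode, 99L) # binary pure-birth topology
  expect_true(all(t1$edge.length > 0))

  t3 <- simulate_tree(2, seed = 1)
  expect_gt(patristic_distances(t3)[1, 2], 0)
  expect_error(simulate_tree(1, seed = 1), "at least 2")
})

test_that("Brownian traits have the additive variance of the process", {
  # sister tips joined by terminal branches of lengths 1 and 2: the trait
  # difference has variance rate * 3
  tree <- ape::read.tree(text = "(A:1,B:2):0;")
  rate <- 0.7
  set.seed(99)
  diffs <- replicate(4000, {
    tr <- simulate_traits(tree, rate = rate)
    tr["A"] - tr["B"]
  })
  expect_equal(mean(diffs), 0, tolerance = 0.1)
  # 3 MC SEs for a variance estimate: var * sqrt(2/(n-1))
  expect_lt(abs(var(diffs) - rate * 3), 3 * rate * 3 * sqrt(2 / 3999))

  near_zero <- simulate_traits(tree, rate = 1e-12, seed = 1)
  expect_true(all(abs(near_zero) < 1e-4))
  expect_error(simulate_traits(tree, rate = 0), "positive")
})

test_that("regime tables conserve library size and are seed-deterministic", {
  tree <- simulate_tree(50, seed = 3)
  for (rg in c("drift", "dispersal_limitation", "homogenizing_dispersal")) {
    spec <- regime_spec(rg, n_samples = 8, n_otus = 50, library_size = 700,
                        generations = 5, seed = 11)
    tab <- simulate_regime(spec, tree)
    expect_true(all(rowSums(tab) == 700), info = rg)
    tab2 <- simulate_regime(spec, tree)
    expect_identical(unclass(tab)[, ], unclass(tab2)[, ], info = rg)
  }
  spec <- regime_spec("selection", n_samples = 8, n_otus = 50,
                      library_size = 700, sigma = 0.5, seed = 11)
  tab <- simulate_regime(spec, tree)
  expect_true(all(rowSums(tab) == 700))
})

test_that("selection collapses to the trait-nearest OTU as niche breadth -> 0", {
  tree <- simulate_tree(40, seed = 5)
  traits <- simulate_traits(tree, rate = 1, seed = 6)
  # optima placed exactly on two OTUs' trait values, far tighter than any
  # trait gap, so each sample should be nearly monodominant for that OTU
  chosen <- names(sort(traits)[c(10, 30)])
  spec <- regime_spec("selection", n_samples = 2, n_otus = 40,
                      library_size = 1000, sigma = 1e-3, seed = 8)
  tab <- simulate_regime(spec, tree, env_optima = unname(traits[chosen]),
                         traits = traits)
  for (j in 1:2) expect_gt(tab[j, chosen[j]] / 1000, 0.99)
})

test_that("sustained drift erodes richness relative to a fresh draw", {
  tree <- simulate_tree(100, seed = 21)
  rich <- function(g, seed) {
    spec <- regime_spec("drift", n_samples = 2, n_otus = 100,
                        library_size = 1000, generations = g, seed = seed)
    mean(rowSums(simulate_regime(spec, tree) > 0))
  }
  seeds <- 1:30
  r0 <- vapply(seeds, function(s) rich(0, s), numeric(1))
  r500 <- vapply(seeds, function(s) rich(500, s + 1000), numeric(1))
  expect_lt(mean(r500), mean(r0))
})

test_that("the mesocosm design yields 144 samples with the warming contrasts", {
  fix <- build_mesocosm_fixture(mesocosm_design(n_otus = 120,
                                                library_size = 2000),
                                seed = 31)
  expect_equal(nrow(fix$table), 18 * 4 * 2)
  expect_equal(ncol(fix$table), 120L)
  expect_equal(nrow(fix$frame), 144L)
  expect_true(all(rowSums(fix$table) == 2000))

  w <- fix$frame[fix$frame$habitat == "water", ]
  mt <- tapply(w$temperature, w$treatment, mean)
  expect_equal(unname(mt["T"] - mt["C"]), 4, tolerance = 0.5)
  expect_equal(unname(mt["H"] - mt["T"]), 0, tolerance = 0.5)
  st <- tapply(w$temperature, w$treatment, sd)
  expect_gt(st[["H"]], st[["T"]])

  # ground truth covers every within-habitat pair
  expect_equal(nrow(fix$truth), 2 * choose(72, 2))
  expect_setequal(unique(fix$truth$regime), c("selection", "drift"))
})

test_that("fixtures round-trip through the data_io readers", {
  design <- mesocosm_design(n_tanks = 3, n_otus = 40, library_size = 300)
  fix <- build_mesocosm_fixture(design, seed = 77)
  dir <- withr::local_tempdir()
  paths <- write_fixture(fix, dir)
  tab <- suppressMessages(read_otu_table(paths["table"]))
  expect_identical(unclass(tab)[, ], unclass(fix$table)[, ])
  frame <- read_sample_frame(paths["metadata"])
  expect_equal(frame$sample_id, fix$frame$sample_id)
  tree <- read_tree(paths["tree"])
  expect_setequal(tree$tip.label, colnames(fix$table))

  fix2 <- build_mesocosm_fixture(design, seed = 77)
  expect_identical(unclass(fix$table)[, ], unclass(fix2$table)[, ])
})

test_that("regime specs validate their parameters", {
  expect_error(regime_spec("selection", sigma = NULL), "sigma")
  expect_error(regime_spec("drift", migration = 1.2), "migration")
  expect_error(regime_spec("drift", generations = -1), "generations")
  expect_error(regime_spec("drift", library_size = 0), "library_size")
  expect_error(regime_spec("dispersal_limitation", n_patches = 1),
               "n_patches")
})
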