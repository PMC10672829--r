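# Synthetic mesocosm communities with known assembly regimes. The generator
# produces the three inputs the pipeline consumes (OTU table, tree, sample
# metadata) plus ground-truth pair labels, so the downstream null models can
# be validated against communities whose assembly process is known.

#' Simulate a pure-birth (Yule) phylogeny
#'
#' Constant-rate birth process, so internode waiting times are exponential;
#' tips are labelled `OTU_1 ... OTU_n`. Deterministic under a fixed seed.
#'
#' @param n_tips number of tips (>= 2).
#' @param seed integer seed.
#' @return an [ape::phylo] tree with branch lengths.
#' @export
simulate_tree <- function(n_tips, seed) {
  if (n_tips < 2) stop("need at least 2 tips")
  set.seed(seed)
  tree <- ape::rphylo(n_tips, birth = 1, death = 0)
  tree$tip.label <- paste0("OTU_", seq_len(n_tips))
  tree
}

#' Simulate a Brownian-motion trait on a tree
#'
#' Evolves a niche trait from root value 0 with variance accumulating at
#' `rate` per unit branch length, so closely related OTUs share similar
#' niches — the phylogenetic conservatism that makes selection visible to
#' nearest-taxon statistics.
#'
#' @param tree an [ape::phylo] with branch lengths.
#' @param rate Brownian variance per unit branch length (> 0).
#' @param seed optional integer seed.
#' @return named numeric vector of tip trait values.
#' @export
simulate_traits <- function(tree, rate = 1, seed = NULL) {
  if (rate <= 0) stop("rate must be positive")
  if (!is.null(seed)) set.seed(seed)
  ape::rTraitCont(tree, model = "BM", sigma = sqrt(rate), root.value = 0)
}

.regimes <- c("selection", "drift", "dispersal_limitation",
              "homogenizing_dispersal")

#' Specification of one assembly regime
#'
#' @param regime one of selection, drift, dispersal_limitation,
#'   homogenizing_dispersal.
#' @param n_samples,n_otus,library_size community dimensions.
#' @param sigma niche breadth of the Gaussian selection kernel, in trait
#'   units (selection only; required there).
#' @param generations rounds of multinomial resampling (drift strength). The
#'   default keeps drift-regime turnover close to single-draw null assembly;
#'   many more rounds accumulate divergence that mimics dispersal limitation.
#' @param migration per-generation mixing fraction with the global mean pool,
#'   in \[0, 1\] (homogenizing dispersal).
#' @param n_patches number of isolated patches (dispersal limitation);
#'   samples are assigned to patches round-robin.
#' @param seed integer seed.
#' @return validated list of class `"regime_spec"`.
#' @export
regime_spec <- function(regime, n_samples = 12, n_otus = 200,
                        library_size = 2000, sigma = NULL, generations = 5,
                        migration = 0.9, n_patches = 4, seed = 1) {
  regime <- match.arg(regime, .regimes)
  if (library_size < 1) stop("library_size must be >= 1")
  if (generations < 0) stop("generations must be >= 0")
  if (migration < 0 || migration > 1) stop("migration must lie in [0, 1]")
  if (regime == "dispersal_limitation" &&
      (n_patches < 2 || n_patches > n_samples))
    stop("n_patches must lie in [2, n_samples]")
  if (regime == "selection" && (is.null(sigma) || sigma <= 0))
    stop("selection regime requires a positive niche breadth sigma")
  structure(list(regime = regime, n_samples = n_samples, n_otus = n_otus,
                 library_size = library_size, sigma = sigma,
                 generations = generations, migration = migration,
                 n_patches = n_patches, seed = seed),
            class = "regime_spec")
}

# lognormal metacommunity rank-abundance curve (heavy tail)
.metacommunity <- function(n_otus) {
  p <- rlnorm(n_otus, meanlog = 0, sdlog = 1.5)
  p / sum(p)
}

.drift_counts <- function(p0, generations, library_size) {
  p <- p0
  for (g in seq_len(generations)) {
    x <- drop(rmultinom(1L, library_size, p))
    p <- x / library_size
  }
  drop(rmultinom(1L, library_size, p))
}

#' Simulate an OTU table under one assembly regime
#'
#' Regime semantics, all returning integer counts with row sums equal to
#' `library_size`:
#' * selection: sampling weight of OTU k in sample j is
#'   `base_k * exp(-(trait_k - optimum_j)^2 / (2 sigma^2))`; samples sharing
#'   an optimum are under homogeneous selection, samples with divergent
#'   optima under variable selection.
#' * drift: each sample evolves independently from the common metacommunity
#'   by `generations` rounds of multinomial resampling at population size
#'   `library_size`, then a final multinomial draw.
#' * dispersal_limitation: drift between isolated patches, each patch seeded
#'   from a disjoint subset of the metacommunity; samples are assigned to
#'   `n_patches` patches round-robin, so between-patch pairs share no source
#'   taxa while within-patch pairs drift from a common pool.
#' * homogenizing_dispersal: each generation every sample's pool is
#'   resampled (drift) and then replaced by `(1 - m) * own + m * global
#'   mean`, with `m` near 1, so pools converge while the final sequencing
#'   draw keeps ordinary sampling noise.
#'
#' @param spec a [regime_spec()].
#' @param tree phylogeny whose tip count equals `spec$n_otus`.
#' @param env_optima per-sample niche optima (selection only); defaults to
#'   four balanced environment levels at -1.5, -0.5, +0.5 and +1.5 trait
#'   standard deviations, emulating contrasting habitats along a gradient.
#' @param traits named tip-trait vector; simulated on `tree` if missing.
#' @return an [otu_table()] with attributes `regime`, `optima`, `traits`.
#' @export
simulate_regime <- function(spec, tree, env_optima = NULL, traits = NULL) {
  stopifnot(inherits(spec, "regime_spec"))
  if (ape::Ntip(tree) != spec$n_otus)
    stop("tree has ", ape::Ntip(tree), " tips but spec$n_otus = ", spec$n_otus)
  set.seed(spec$seed)
  n <- spec$n_samples
  base <- .metacommunity(spec$n_otus)
  lib <- spec$library_size
  counts <- matrix(0L, n, spec$n_otus,
                   dimnames = list(sprintf("S%02d", seq_len(n)),
                                   tree$tip.label))
  optima <- NULL
  if (spec$regime == "selection") {
    if (is.null(traits)) traits <- simulate_traits(tree, rate = 1)
    traits <- traits[tree$tip.label]
    if (is.null(env_optima))
      env_optima <- sort(rep(c(-1.5, -0.5, 0.5, 1.5) * sd(traits),
                             length.out = n))
    if (length(env_optima) != n) stop("need one optimum per sample")
    optima <- env_optima
    for (j in seq_len(n)) {
      w <- base * exp(-(traits - optima[j])^2 / (2 * spec$sigma^2))
      if (sum(w) <= 0) stop("selection kernel annihilated every OTU")
      counts[j, ] <- drop(rmultinom(1L, lib, w))
    }
  } else if (spec$regime == "drift") {
    for (j in seq_len(n))
      counts[j, ] <- .drift_counts(base, spec$generations, lib)
  } else if (spec$regime == "dispersal_limitation") {
    # OTUs dealt round-robin by abundance rank so patch mass is comparable
    k <- spec$n_patches
    patch_of_otu <- (rank(-base, ties.method = "first") - 1L) %% k + 1L
    patch_of_sample <- (seq_len(n) - 1L) %% k + 1L
    for (j in seq_len(n)) {
      p0 <- ifelse(patch_of_otu == patch_of_sample[j], base, 0)
      p0 <- p0 / sum(p0)
      counts[j, ] <- .drift_counts(p0, spec$generations, lib)
    }
  } else { # homogenizing_dispersal
    p <- t(vapply(seq_len(n), function(j)
      drop(rmultinom(1L, lib, base)) / lib, numeric(spec$n_otus)))
    m <- spec$migration
    for (g in seq_len(spec$generations)) {
      for (j in seq_len(n))
        p[j, ] <- drop(rmultinom(1L, lib, p[j, ])) / lib
      pbar <- colMeans(p)
      p <- (1 - m) * p + matrix(pbar, n, spec$n_otus, byrow = TRUE) * m
    }
    for (j in seq_len(n))
      counts[j, ] <- drop(rmultinom(1L, lib, p[j, ]))
  }
  out <- otu_table(counts)
  attr(out, "regime") <- spec$regime
  attr(out, "optima") <- optima
  attr(out, "traits") <- traits
  out
}

#' Mesocosm experimental design
#'
#' Defaults mirror an 18-tank, three-scenario warming experiment: 6 replicate
#' tanks per treatment (C ambient, T constant +4 degC, H heatwave
#' fluctuating +/-4 degC around T so the annual mean matches T), sampled in
#' four seasons in two habitats (water column and sediment).
#'
#' @param n_tanks total tanks; must be divisible by 3.
#' @param n_otus,library_size community dimensions per habitat.
#' @param base_temp_mean,base_temp_amplitude seasonal sinusoid of the ambient
#'   water temperature (degC).
#' @param warming_offset constant warming above ambient (degC).
#' @param heatwave_amplitude seasonal oscillation of H around T (degC).
#' @param noise_sd measurement noise on covariates.
#' @return list of class `"mesocosm_design"`.
#' @export
mesocosm_design <- function(n_tanks = 18, n_otus = 500, library_size = 10000,
                            base_temp_mean = 19.5, base_temp_amplitude = 8,
                            warming_offset = 4, heatwave_amplitude = 4,
                            noise_sd = 0.5) {
  if (n_tanks %% 3 != 0) stop("n_tanks must be divisible by 3 treatments")
  structure(list(n_tanks = n_tanks, n_otus = n_otus,
                 library_size = library_size,
                 base_temp_mean = base_temp_mean,
                 base_temp_amplitude = base_temp_amplitude,
                 warming_offset = warming_offset,
                 heatwave_amplitude = heatwave_amplitude,
                 noise_sd = noise_sd),
            class = "mesocosm_design")
}

# seasonal shape of the ambient temperature (relative to the annual mean)
.season_phase <- c(spring = 0, summer = 1, autumn = 0, winter = -1)
# H oscillates +/- heatwave_amplitude around T with zero annual mean
.heatwave_phase <- c(spring = 1, summer = -1, autumn = 1, winter = -1)

#' Generate a full mesocosm fixture (table, metadata, tree, truth)
#'
#' Builds tanks x seasons x habitats samples with season-dependent
#' environmental covariates, treatment temperature offsets, and communities
#' assembled under a per-habitat regime. By default the water community
#' assembles under temperature-linked selection (optima follow the scaled
#' water temperature, so warming shifts composition) and the sediment
#' community under neutral drift.
#'
#' @param design a [mesocosm_design()].
#' @param regimes named list habitat -> [regime_spec()]; `n_samples` of each
#'   is forced to tanks x seasons. Selection sigma defaults to 0.3 x the
#'   trait standard deviation when unset.
#' @param seed master seed.
#' @return list of class `"mesocosm_fixture"`: `table` (144 x n_otus
#'   [otu_table()]), `frame` (metadata), `tree`, `truth` (within-habitat pair
#'   regime labels), `traits`.
#' @export
build_mesocosm_fixture <- function(design = mesocosm_design(),
                                   regimes = NULL, seed = 1) {
  seasons <- .seasons
  n_hab_samples <- design$n_tanks * length(seasons)
  tree <- simulate_tree(design$n_otus, seed = seed)
  traits <- simulate_traits(tree, rate = 1, seed = seed + 1L)
  if (is.null(regimes)) {
    regimes <- list(
      water = regime_spec("selection", n_samples = n_hab_samples,
                          n_otus = design$n_otus,
                          library_size = design$library_size,
                          sigma = 0.3 * sd(traits), seed = seed + 2L),
      sediment = regime_spec("drift", n_samples = n_hab_samples,
                             n_otus = design$n_otus,
                             library_size = design$library_size,
                             seed = seed + 3L))
  }
  if (!setequal(names(regimes), .habitats))
    stop("regimes must be named by habitat: ", paste(.habitats, collapse = ", "))
  per_trt <- design$n_tanks / 3L
  treatment_of_tank <- rep(.treatments, each = per_trt)

  set.seed(seed + 10L)
  frames <- list(); tables <- list(); truths <- list()
  for (hab in .habitats) {
    grid <- expand.grid(tank = seq_len(design$n_tanks), season = seasons,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    grid$treatment <- treatment_of_tank[grid$tank]
    grid$habitat <- hab
    grid$sample_id <- sprintf("%s_%s%02d_%s", substr(hab, 1, 1),
                              grid$treatment, grid$tank, grid$season)
    base_t <- design$base_temp_mean +
      design$base_temp_amplitude * .season_phase[grid$season]
    trt_off <- ifelse(grid$treatment == "C", 0, design$warming_offset)
    hw <- ifelse(grid$treatment == "H",
                 design$heatwave_amplitude * .heatwave_phase[grid$season], 0)
    temp <- base_t + trt_off + hw + rnorm(nrow(grid), 0, design$noise_sd)
    warm <- trt_off + hw # realized warming relative to ambient
    nn <- nrow(grid)
    ns <- design$noise_sd
    env <- data.frame(
      temperature = temp,
      TN = pmax(0.05, 1.5 + 0.4 * .season_phase[grid$season] + 0.08 * warm +
                  rnorm(nn, 0, 0.1 * ns)),
      TP = pmax(0.005, 0.08 + 0.02 * .season_phase[grid$season] +
                  rnorm(nn, 0, 0.01 * ns)),
      NH4_N = pmax(0.005, 0.3 + 0.05 * .season_phase[grid$season] +
                     0.05 * warm + rnorm(nn, 0, 0.02 * ns)),
      NO3_N = pmax(0.005, 0.5 - 0.1 * .season_phase[grid$season] -
                     0.02 * warm + rnorm(nn, 0, 0.03 * ns)),
      NO2_N = pmax(0.001, 0.05 + 0.01 * .season_phase[grid$season] +
                     rnorm(nn, 0, 0.005 * ns)))
    if (hab == "water") {
      env$PO4_P <- pmax(0.001, 0.02 + rnorm(nn, 0, 0.004 * ns))
      env$pH <- 8.2 + 0.1 * .season_phase[grid$season] + rnorm(nn, 0, 0.05 * ns)
      env$DO <- pmax(0.5, 9 - 0.15 * (temp - design$base_temp_mean) +
                       rnorm(nn, 0, 0.2 * ns))
      env$conductivity <- pmax(50, 400 + 20 * .season_phase[grid$season] +
                                 5 * warm + rnorm(nn, 0, 5 * ns))
      env$Chl_a <- pmax(0.1, 15 + 8 * .season_phase[grid$season] + 1.5 * warm +
                          rnorm(nn, 0, ns))
      env$IP <- NA_real_
    } else {
      env$PO4_P <- NA_real_
      env$pH <- NA_real_
      env$DO <- NA_real_
      env$conductivity <- NA_real_
      env$Chl_a <- NA_real_
      env$IP <- pmax(1, 120 + 10 * .season_phase[grid$season] +
                       rnorm(nn, 0, 2 * ns))
    }
    frame <- cbind(grid[c("sample_id", "habitat", "treatment", "season",
                          "tank")], env)
    spec <- regimes[[hab]]
    spec$n_samples <- nn
    spec$n_otus <- design$n_otus
    optima <- NULL
    if (spec$regime == "selection")
      optima <- as.numeric(scale(temp)) * sd(traits)
    tab <- simulate_regime(spec, tree, env_optima = optima, traits = traits)
    rownames(tab) <- frame$sample_id
    prs <- combn(frame$sample_id, 2L)
    truths[[hab]] <- data.frame(sample_a = prs[1, ], sample_b = prs[2, ],
                                regime = spec$regime)
    frames[[hab]] <- frame
    tables[[hab]] <- unclass(tab)
  }
  table <- otu_table(do.call(rbind, tables))
  frame <- do.call(rbind, c(frames, make.row.names = FALSE))
  structure(list(table = table, frame = frame, tree = tree,
                 truth = do.call(rbind, c(truths, make.row.names = FALSE)),
                 traits = traits, design = design, seed = seed),
            class = "mesocosm_fixture")
}

#' Write a fixture to disk in the pipeline's input formats
#'
#' Emits `table.tsv`, `metadata.csv`, `tree.nwk` and `truth.csv` under `dir`.
#'
#' @param fixture a [build_mesocosm_fixture()] result.
#' @param dir output directory (created if needed).
#' @return invisibly the four paths.
#' @export
write_fixture <- function(fixture, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(table = file.path(dir, "table.tsv"),
             metadata = file.path(dir, "metadata.csv"),
             tree = file.path(dir, "tree.nwk"),
             truth = file.path(dir, "truth.csv"))
  write_otu_table(fixture$table, paths["table"])
  write_sample_frame(fixture$frame, paths["metadata"])
  # 17 significant digits so branch lengths round-trip exactly
  ape::write.tree(fixture$tree, paths["tree"], digits = 17)
  write.csv(fixture$truth, paths["truth"], row.names = FALSE, quote = FALSE)
  invisible(paths)
}
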