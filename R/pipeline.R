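# End-to-end orchestration: from (table, tree, metadata) or a synthetic
# fixture to the full set of report tables, with a manifest that reproduces
# every output bit-for-bit.

#' Pipeline configuration
#'
#' @param table,tree,metadata in-memory inputs ([otu_table()], [ape::phylo],
#'   metadata data.frame) or `NULL` when paths are given.
#' @param table_path,tree_path,metadata_path on-disk inputs (TSV / newick /
#'   CSV), read with the `data_io` readers.
#' @param out_dir report directory (created if needed).
#' @param rarefy_depth `"min"` (per-habitat minimum library), a fixed integer
#'   depth, or `NULL` to skip rarefaction.
#' @param network_grouping metadata factors defining one network per group
#'   (default habitat x treatment, pooling seasons).
#' @param assembly_grouping factors defining the pair groups for process
#'   partitioning (default habitat x treatment x season).
#' @param env_variables covariates for the betaNTI Mantel table; defaults to
#'   every covariate with complete values within a habitat.
#' @param r_threshold,alpha network edge thresholds.
#' @param n_null_bnti,n_null_rc,n_perm randomization effort per stage.
#' @param weighted_bnti abundance-weight betaMNTD.
#' @param seed master seed; every stochastic stage derives its own seed from
#'   it.
#' @return list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(table = NULL, tree = NULL, metadata = NULL,
                            table_path = NULL, tree_path = NULL,
                            metadata_path = NULL, out_dir,
                            rarefy_depth = "min",
                            network_grouping = c("habitat", "treatment"),
                            assembly_grouping = c("habitat", "treatment",
                                                  "season"),
                            env_variables = NULL,
                            r_threshold = 0.6, alpha = 0.05,
                            n_null_bnti = 999, n_null_rc = 999,
                            n_perm = 999, weighted_bnti = TRUE, seed = 1) {
  structure(list(table = table, tree = tree, metadata = metadata,
                 table_path = table_path, tree_path = tree_path,
                 metadata_path = metadata_path, out_dir = out_dir,
                 rarefy_depth = rarefy_depth,
                 network_grouping = network_grouping,
                 assembly_grouping = assembly_grouping,
                 env_variables = env_variables,
                 r_threshold = r_threshold, alpha = alpha,
                 n_null_bnti = n_null_bnti, n_null_rc = n_null_rc,
                 n_perm = n_perm, weighted_bnti = weighted_bnti,
                 seed = seed),
            class = "pipeline_config")
}

.stage <- function(name, log_path, expr) {
  cat(sprintf("[%s] stage: %s\n", format(Sys.time(), "%H:%M:%S"), name),
      file = log_path, append = TRUE)
  tryCatch(expr, error = function(e)
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
}

.topology_columns <- c("group", "nodes", "edges", "average_degree",
                       "average_transitivity",
                       "average_clustering_coefficient",
                       "average_path_length", "diameter", "modularity",
                       "graph_density", "positive_relationship_pct",
                       "on_largest_component")

#' Run the full analysis pipeline
#'
#' Stages: input loading and validation; per-habitat rarefaction to the
#' minimum library; alpha diversity; Bray-Curtis matrices; PERMANOVA of
#' treatment and season effects; co-occurrence networks with the topology
#' panel per group; per-sample NTI; betaNTI + RCbray and the five-process
#' partition per group; Mantel correlations of betaNTI against environmental
#' covariates. All outputs are plain-text tables under `config$out_dir`,
#' together with `manifest.json` (full parameter set and derived seeds) and
#' `pipeline.log`. Identical config + seed reproduces every file
#' byte-for-byte.
#'
#' @param config a [pipeline_config()].
#' @return invisibly the output directory.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out, "pipeline.log")
  cat("", file = log_path)
  seeds <- list(rarefy = config$seed + 101L, bnti = config$seed + 202L,
                rc = config$seed + 303L, permanova = config$seed + 404L,
                mantel = config$seed + 505L, modularity = config$seed + 606L)

  inputs <- .stage("load", log_path, {
    table <- config$table %||% read_otu_table(config$table_path)
    tree <- config$tree %||% read_tree(config$tree_path)
    frame <- config$metadata %||% read_sample_frame(config$metadata_path)
    validate_dataset(table, frame, tree, phylo = TRUE)
    list(table = table, frame = frame, tree = tree)
  })
  table <- inputs$table; frame <- inputs$frame; tree <- inputs$tree
  frame <- frame[match(rownames(table), frame$sample_id), , drop = FALSE]
  habitats <- unique(frame$habitat)

  by_habitat <- .stage("rarefaction", log_path, {
    lapply(setNames(habitats, habitats), function(hab) {
      sub <- otu_table(unclass(table)[frame$habitat == hab, , drop = FALSE])
      depth <- config$rarefy_depth
      if (is.null(depth)) return(sub)
      if (identical(depth, "min")) depth <- min(rowSums(sub))
      rarefy(sub, depth, seed = seeds$rarefy)
    })
  })

  .stage("alpha_diversity", log_path, {
    alpha <- do.call(rbind, lapply(by_habitat, alpha_diversity))
    write_report_table(alpha, file.path(out, "alpha_diversity.tsv"))
  })

  bc <- .stage("bray_curtis", log_path, {
    lapply(setNames(habitats, habitats), function(hab) {
      m <- bray_curtis(by_habitat[[hab]])
      write_matrix_tsv(m, file.path(out, paste0("bray_curtis_", hab, ".tsv")))
      m
    })
  })

  .stage("permanova", log_path, {
    rows <- list()
    for (hab in habitats) {
      fr <- frame[match(rownames(bc[[hab]]), frame$sample_id), ]
      for (fac in c("treatment", "season")) {
        if (length(unique(fr[[fac]])) < 2) next
        fit <- permanova(bc[[hab]], fr[[fac]], n_perm = config$n_perm,
                         seed = seeds$permanova)
        rows[[paste(hab, fac)]] <- data.frame(
          habitat = hab, factor = fac, pseudo_F = fit$statistic,
          r_squared = fit$r_squared, p = fit$p_value,
          n_permutations = config$n_perm)
      }
    }
    write_report_table(do.call(rbind, c(rows, make.row.names = FALSE)),
                       file.path(out, "permanova.tsv"))
  })

  .stage("networks", log_path, {
    grp <- interaction(frame[config$network_grouping], sep = ".", drop = TRUE)
    topo <- list()
    for (g in levels(grp)) {
      ids <- frame$sample_id[grp == g]
      hab <- unique(frame$habitat[grp == g])[1]
      sub <- unclass(by_habitat[[hab]])
      sub <- otu_table(sub[intersect(rownames(sub), ids), , drop = FALSE])
      res <- tryCatch({
        filt <- suppressMessages(filter_otus(sub))
        edges <- correlation_edges(filt, r_threshold = config$r_threshold,
                                   alpha = config$alpha)
        net <- build_network(edges, table = filt)
        write_edge_list(net, file.path(out, paste0("network_", g)))
        cbind(group = g, topology(net, modularity_seed = seeds$modularity))
      }, error = function(e) {
        cat("network group", g, "skipped:", conditionMessage(e), "\n",
            file = log_path, append = TRUE)
        NULL
      })
      if (!is.null(res)) topo[[g]] <- res
    }
    topo <- if (length(topo))
      do.call(rbind, c(topo, make.row.names = FALSE))[, .topology_columns]
    else
      setNames(data.frame(matrix(nrow = 0, ncol = length(.topology_columns))),
               .topology_columns)
    write_report_table(topo, file.path(out, "network_topology.tsv"))
  })

  assembly <- .stage("assembly", log_path, {
    parts <- list(); ntis <- list(); mantels <- list()
    for (hab in habitats) {
      tab <- by_habitat[[hab]]
      nti <- nti_table(tab, tree = tree, n_null = config$n_null_bnti,
                       seed = seeds$bnti)
      nti$habitat <- hab
      ntis[[hab]] <- nti
      bn <- beta_nti(tab, tree = tree, weighted = config$weighted_bnti,
                     n_null = config$n_null_bnti, seed = seeds$bnti)
      rc <- raup_crick_bray(tab, n_null = config$n_null_rc, seed = seeds$rc)
      write_matrix_tsv(bn$bnti, file.path(out, paste0("bnti_", hab, ".tsv")))
      write_matrix_tsv(rc$rc, file.path(out, paste0("rcbray_", hab, ".tsv")))
      fr <- frame[frame$habitat == hab, ]
      part <- partition_processes(bn, rc, fr,
        grouping = setdiff(config$assembly_grouping, "habitat"))
      part$proportions$habitat <- hab
      part$summary$habitat <- hab
      part$bnti_values$habitat <- hab
      parts[[hab]] <- part
      env <- config$env_variables %||% {
        cand <- setdiff(names(fr), c("sample_id", "habitat", "treatment",
                                     "season", "tank"))
        cand[vapply(cand, function(v) !anyNA(fr[[v]]), logical(1))]
      }
      mt <- mantel_env_table(bn, fr, env, n_perm = config$n_perm,
                             seed = seeds$mantel)
      mt$habitat <- hab
      mantels[[hab]] <- mt
    }
    write_report_table(do.call(rbind, c(ntis, make.row.names = FALSE)),
                       file.path(out, "nti_per_sample.tsv"))
    write_report_table(
      do.call(rbind, lapply(parts, function(p) p$proportions)),
      file.path(out, "process_proportions.tsv"))
    write_report_table(
      do.call(rbind, lapply(parts, function(p) p$summary)),
      file.path(out, "process_summary.tsv"))
    write_report_table(
      do.call(rbind, lapply(parts, function(p) p$bnti_values)),
      file.path(out, "bnti_distribution.tsv"))
    write_report_table(do.call(rbind, c(mantels, make.row.names = FALSE)),
                       file.path(out, "mantel_env.tsv"))
    parts
  })

  .stage("manifest", log_path, {
    manifest <- list(
      package_version = as.character(utils::packageVersion("assemblage")),
      parameters = unclass(config)[setdiff(names(config),
                                           c("table", "tree", "metadata"))],
      derived_seeds = seeds,
      n_samples = nrow(table), n_otus = ncol(table))
    jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, null = "null",
                         digits = NA)
  })
  invisible(out)
}

#' Generate a synthetic fixture on disk
#'
#' Thin wrapper over [build_mesocosm_fixture()] + [write_fixture()].
#'
#' @param dir output directory.
#' @param seed master seed.
#' @param design a [mesocosm_design()].
#' @param regimes optional named regime list (see
#'   [build_mesocosm_fixture()]).
#' @return invisibly the written paths.
#' @export
generate_fixture <- function(dir, seed = 1, design = mesocosm_design(),
                             regimes = NULL) {
  fix <- build_mesocosm_fixture(design, regimes = regimes, seed = seed)
  write_fixture(fix, dir)
}
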