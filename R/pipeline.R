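#' Pipeline configuration
#'
#' Collects every setting of a full analysis run. Input is either a pair of
#' file paths (atlas + expression CSV) or a `cohort_spec` for a synthetic
#' cohort. Defaults mirror the standard analysis: thresholds 0.05 and 0.01,
#' Fisher-Z community weights, Louvain communities, top-quartile hubs in >= 3
#' of 4 measures, WC/PC hub cutoffs 1.5 / 0.3 / 0.8, 1000 permutations.
#'
#' @param expression Path to an expression CSV, a `fos_expression`, or a
#'   `cohort_spec`.
#' @param atlas Path to an atlas CSV or a `fos_atlas` (default atlas if NULL
#'   and `expression` is a spec).
#' @param conditions Length-2 character vector: the condition pair whose
#'   networks are compared.
#' @param baseline Baseline condition for normalization.
#' @param thresholds Network p thresholds (duplicates rejected).
#' @param weight_scheme Centrality weights: `"r"` or `"fisher_z"`.
#' @param community_algorithm Passed to [detect_communities()].
#' @param pc_variant Passed to [participation_coefficient()].
#' @param top_fraction,min_measures Hub rule parameters.
#' @param wc_cut,pc_provincial,pc_connector Community-role cutoffs.
#' @param n_perm Permutation count for the centrality test.
#' @param seed Global seed.
#' @param out_dir Output directory.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(expression, atlas = NULL,
                            conditions = c("CFC-5s", "CFC"),
                            baseline = "HC",
                            thresholds = c(0.05, 0.01),
                            weight_scheme = "r",
                            community_algorithm = "multilevel_louvain",
                            pc_variant = "guimera",
                            top_fraction = 0.25, min_measures = 3,
                            wc_cut = 1.5, pc_provincial = 0.3,
                            pc_connector = 0.8,
                            n_perm = 1000, seed = 1L, out_dir = tempfile("fosnet_")) {
  if (anyDuplicated(thresholds)) stop("duplicated thresholds")
  if (length(conditions) != 2) stop("'conditions' must name exactly two conditions")
  structure(
    list(expression = expression, atlas = atlas, conditions = conditions,
         baseline = baseline, thresholds = thresholds,
         weight_scheme = weight_scheme,
         community_algorithm = community_algorithm, pc_variant = pc_variant,
         top_fraction = top_fraction, min_measures = min_measures,
         wc_cut = wc_cut, pc_provincial = pc_provincial,
         pc_connector = pc_connector, n_perm = n_perm, seed = as.integer(seed),
         out_dir = out_dir),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' Scalar settings map directly onto [pipeline_config()] arguments;
#' `expression` and `atlas` are file paths.
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- y[intersect(names(y), names(formals(pipeline_config)))]
  do.call(pipeline_config, args)
}

resolve_inputs <- function(config) {
  atlas <- config$atlas
  if (is.character(atlas)) atlas <- read_atlas(atlas)
  expr <- config$expression
  if (inherits(expr, "cohort_spec")) {
    if (is.null(atlas)) atlas <- expr$atlas
    expr <- generate_cohort(expr)
  } else if (is.character(expr)) {
    if (is.null(atlas)) stop("an atlas is required to read an expression file")
    expr <- read_expression(expr, atlas)
  } else if (inherits(expr, "fos_expression")) {
    if (is.null(atlas)) atlas <- expr$atlas
  } else {
    stop("'expression' must be a path, fos_expression or cohort_spec")
  }
  list(expr = expr, atlas = atlas)
}

#' Run the full analysis pipeline
#'
#' Executes normalization, activation analysis, per-condition correlation
#' matrices, group-connectivity comparison, network construction at every
#' threshold, graph summaries, community/role analysis, centralities and hub
#' identification, stable hubs, and the permutation centrality test; writes
#' all tables, network exports and a JSON manifest into `config$out_dir`.
#' Re-running with the same config and seed reproduces identical outputs.
#'
#' @param config A `pipeline_config`.
#' @return The manifest (list), invisibly; all outputs are files under
#'   `config$out_dir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  inp <- resolve_inputs(config)
  expr <- inp$expr
  atlas <- inp$atlas
  missing_conds <- setdiff(c(config$conditions, config$baseline),
                           unique(expr$animals$condition))
  if (length(missing_conds) > 0) {
    stop("condition(s) not present in the data: ",
         paste(missing_conds, collapse = ", "))
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(...) file.path(config$out_dir, paste0(...))
  files <- character(0)
  log_lines <- character(0)
  say <- function(...) log_lines <<- c(log_lines, paste0(...))

  stage <- function(name, fun) {
    tryCatch(fun(), error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  # normalize
  norm <- stage("normalize", function() normalize_to_baseline(expr, config$baseline))
  write_expression(norm, out("expression_percent_of_baseline.csv"))
  files <- c(files, "expression_percent_of_baseline.csv")
  say("normalized ", nrow(norm$values), " animals to baseline '",
      config$baseline, "'")

  # activation
  act <- stage("activation", function()
    compare_activation(norm, alpha = 0.05, seed = config$seed))
  write_activation(act, out("activation_table.csv"))
  cls <- tryCatch(classify_engagement(act), error = function(e) NULL)
  if (!is.null(cls)) {
    utils::write.csv(cls, out("engagement_classification.csv"),
                     row.names = FALSE)
    files <- c(files, "engagement_classification.csv")
  }
  files <- c(files, "activation_table.csv")

  # connectivity
  corrs <- stage("connectivity", function() {
    lapply(stats::setNames(config$conditions, config$conditions),
           function(cc) correlation_matrix(norm, cc))
  })
  for (cc in config$conditions) {
    write_correlation(corrs[[cc]], out("correlation_", gsub("[^A-Za-z0-9]", "_", cc)))
  }
  gc_cmp <- compare_group_connectivity(corrs[[1]], corrs[[2]], atlas)
  utils::write.csv(gc_cmp, out("group_connectivity_comparison.csv"),
                   row.names = FALSE)
  files <- c(files, "group_connectivity_comparison.csv")

  # networks x thresholds, topology
  hub_sets <- list()
  summaries <- list()
  for (cc in config$conditions) {
    hub_sets[[cc]] <- list()
    for (thr in config$thresholds) {
      tag <- paste0(gsub("[^A-Za-z0-9]", "_", cc), "_p",
                    gsub("\\.", "", format(thr)))
      net <- stage("network", function() build_network(corrs[[cc]], thr))
      write_network(net, out("network_", tag))
      gs <- graph_summary(net)
      summaries[[tag]] <- gs[c("n_nodes", "n_connected", "n_edges", "density",
                               "density_all", "avg_degree",
                               "avg_weighted_degree", "avg_clustering",
                               "global_efficiency", "avg_path_length",
                               "max_eccentricity")]
      part <- stage("topology", function()
        detect_communities(net, config$community_algorithm, seed = config$seed))
      wc <- wc_zscore(net, part)
      pc <- participation_coefficient(net, part, config$pc_variant)
      roles <- classify_roles(wc, pc, config$wc_cut, config$pc_provincial,
                              config$pc_connector)
      part_df <- data.frame(node = names(part$membership),
                            community = unname(part$membership),
                            modularity = part$modularity)
      utils::write.csv(part_df, out("communities_", tag, ".csv"),
                       row.names = FALSE)
      utils::write.csv(roles, out("roles_", tag, ".csv"), row.names = FALSE)
      comp <- as.data.frame.matrix(community_composition(part, atlas))
      utils::write.csv(comp, out("community_composition_", tag, ".csv"))
      ct <- centralities(net, config$weight_scheme)
      hubs <- identify_hubs(ct, config$top_fraction, config$min_measures)
      ct_out <- cbind(ct, as.data.frame(hubs$ranks),
                      hub = ct$node %in% hubs$hubs)
      names(ct_out)[6:9] <- paste0("rank_", c("wdg", "evc", "bet", "clo"))
      utils::write.csv(ct_out, out("centralities_", tag, ".csv"),
                       row.names = FALSE)
      hub_sets[[cc]][[as.character(thr)]] <- hubs$hubs
      files <- c(files, paste0(c("communities_", "roles_",
                                 "community_composition_", "centralities_"),
                               tag, ".csv"),
                 paste0("network_", tag, c(".graphml", "_edges.csv")))
      say("network ", tag, ": ", gs$n_edges, " edges, density ",
          round(gs$density, 3))
    }
  }
  stable <- lapply(hub_sets, function(s) stable_hubs(s))
  utils::write.csv(
    data.frame(condition = rep(names(stable), lengths(stable)),
               hub = unlist(stable), row.names = NULL),
    out("stable_hubs.csv"), row.names = FALSE)
  files <- c(files, "stable_hubs.csv")

  # permutation comparison
  perm <- stage("permutation", function()
    permutation_centrality_test(norm, config$conditions[1],
                                config$conditions[2],
                                p_thresholds = config$thresholds,
                                n_perm = config$n_perm, seed = config$seed,
                                weight_scheme = config$weight_scheme))
  write_permutation(perm, out("permutation_centrality"))
  files <- c(files, "permutation_centrality.csv")

  writeLines(log_lines, out("run_log.txt"))
  manifest <- list(
    package_version = as.character(utils::packageVersion("fosnet")),
    seed = config$seed,
    parameters = config[c("conditions", "baseline", "thresholds",
                          "weight_scheme", "community_algorithm", "pc_variant",
                          "top_fraction", "min_measures", "wc_cut",
                          "pc_provincial", "pc_connector", "n_perm")],
    summaries = summaries,
    stable_hubs = stable,
    files = as.list(stats::setNames(
      tools::md5sum(file.path(config$out_dir, files)), files))
  )
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest)
}
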