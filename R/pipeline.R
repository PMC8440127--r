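#' Assemble a run configuration
#'
#' A run either loads the three input tables from disk or simulates them
#' (exactly one of `strains`/`groups`/`cog_map` paths or `simulate` must
#' be given).
#'
#' @param strains,groups,cog_map Input TSV paths (all three together).
#' @param simulate A [sim_config()] object (alternative to input paths).
#' @param n_core n-core percent threshold (default 97).
#' @param asu_impute `"exclude"` or `"global_mean"` (see
#'   [compute_asu()]).
#' @param network_threshold Shared-ortholog edge threshold (default 5).
#' @param community_method `"components"` or `"greedy_modularity"`.
#' @param bh_alpha FDR level for the COG comparisons.
#' @param out_dir Output directory, or `NULL` to skip writing files.
#' @param seed Seed recorded for provenance (and forwarded to the
#'   simulator when `simulate` is given without its own explicit seed).
#' @return List of class `gec_run_config`.
#' @export
gec_config <- function(strains = NULL, groups = NULL, cog_map = NULL,
                       simulate = NULL, n_core = 97,
                       asu_impute = "exclude", network_threshold = 5,
                       bh_alpha = 0.05, community_method = "components",
                       out_dir = NULL, seed = 1) {
  has_paths <- !is.null(strains) || !is.null(groups) || !is.null(cog_map)
  if (has_paths && !is.null(simulate))
    abort("give either input paths or a simulate block, not both")
  if (!has_paths && is.null(simulate))
    abort("give input paths (strains, groups, cog_map) or a simulate block")
  if (has_paths && (is.null(strains) || is.null(groups) || is.null(cog_map)))
    abort("all three input paths (strains, groups, cog_map) are required")
  if (!(n_core %% 1 == 0) || n_core < 91 || n_core > 100)
    abort("n_core must be an integer in [91, 100]")
  if (network_threshold < 0) abort("network_threshold must be >= 0")
  if (bh_alpha <= 0 || bh_alpha >= 1) abort("bh_alpha must be in (0, 1)")
  structure(list(strains = strains, groups = groups, cog_map = cog_map,
                 simulate = simulate, n_core = n_core,
                 asu_impute = asu_impute,
                 network_threshold = network_threshold,
                 bh_alpha = bh_alpha, community_method = community_method,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "gec_run_config")
}

#' Read a run configuration from YAML
#'
#' The YAML mirrors the arguments of [gec_config()]; a `simulate` block
#' holds [sim_config()] fields.
#'
#' @param path YAML file path.
#' @return A `gec_run_config`.
#' @export
read_gec_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$simulate)) {
    sim_args <- y$simulate
    if (!is.null(sim_args$community_size_range))
      sim_args$community_size_range <- as.numeric(sim_args$community_size_range)
    y$simulate <- do.call(sim_config, sim_args)
  }
  do.call(gec_config, y)
}

#' Run the whole analysis end-to-end
#'
#' Wires every stage in order: load or simulate inputs, drop
#' strain-specific singletons, partition core/accessory at the n-core
#' threshold, compute ASU and classify generalist/specialist clusters,
#' profile COG ratios with pairwise Welch tests and BH correction, fit
#' the two feature regressions, build the generalist and specialist
#' shared-ortholog networks, extract communities and measure genus
#' mixing. Writes the stage TSVs, network exports and a machine-readable
#' JSON report under `config$out_dir` when set. Re-running with the same
#' config and seed reproduces every output byte-identically.
#'
#' @param config A `gec_run_config` from [gec_config()] or
#'   [read_gec_config()], or a YAML path.
#' @param quiet Suppress progress messages.
#' @return List of class `gec_run`: all stage objects plus `report` (the
#'   JSON-ready summary).
#' @export
run_gec <- function(config, quiet = FALSE) {
  if (is.character(config)) config <- read_gec_config(config)
  stopifnot(inherits(config, "gec_run_config"))
  say <- function(fmt, ...) if (!quiet) message(sprintf(fmt, ...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      abort("stage '%s' failed: %s", name, conditionMessage(e)))
  }

  if (!is.null(config$simulate)) {
    say("stage simulate")
    sim <- config$simulate
    dataset <- stage("simulate", simulate_gec_dataset(sim))
    strains <- dataset$strains
    clusters <- dataset$clusters
    truth <- dataset$truth
  } else {
    say("stage load")
    strains <- stage("load", read_strain_table(config$strains))
    clusters <- stage("load", read_ortholog_groups(config$groups,
                                                   strains = strains))
    clusters <- stage("load", annotate_cogs(clusters, config$cog_map))
    truth <- NULL
  }

  say("stage singleton filter + n-core")
  nonsingleton <- stage("drop_singletons",
                        suppressMessages(drop_singletons(clusters)))
  pm <- stage("presence", presence_matrix(nonsingleton,
                                          strains = strains$strain_id))
  partition <- stage("compute_ncore",
                     compute_ncore(pm, config$n_core, clusters = nonsingleton))

  say("stage ASU classification")
  su_stats <- stage("strain_su_stats", strain_su_stats(strains))
  asu <- stage("compute_asu",
               compute_asu(nonsingleton, strains, impute = config$asu_impute))
  asu <- stage("classify_clusters", classify_clusters(asu, su_stats))
  scatter <- stage("asu_scatter_summary", asu_scatter_summary(asu))

  say("stage COG statistics")
  gen_ids <- asu$cluster_id[asu$group == "generalist"]
  spe_ids <- asu$cluster_id[asu$group == "specialist"]
  ratio_sets <- list(core = partition$core, accessory = partition$accessory,
                     generalist = gen_ids, specialist = spe_ids)
  ratios <- lapply(ratio_sets, function(ids)
    if (length(ids)) cog_ratios(nonsingleton, ids) else NULL)
  comparisons <- list()
  pairs <- list(c("accessory", "generalist"), c("accessory", "specialist"),
                c("generalist", "specialist"))
  for (pr in pairs) {
    a <- ratio_sets[[pr[1]]]; b <- ratio_sets[[pr[2]]]
    if (length(a) && length(b))
      comparisons[[paste(pr, collapse = "_vs_")]] <-
        stage("compare_cog_sets",
              compare_cog_sets(nonsingleton, a, b, alpha = config$bh_alpha))
  }

  say("stage regressions")
  regressions <- stage("regression", run_feature_regressions(strains))

  say("stage networks")
  networks <- list(); communities <- list(); mixing <- list()
  for (grp in c("generalist", "specialist")) {
    ids <- if (grp == "generalist") gen_ids else spe_ids
    g <- stage("build_gec_network",
               build_gec_network(nonsingleton, ids, strains,
                                 threshold = config$network_threshold,
                                 group = grp))
    networks[[grp]] <- g
    communities[[grp]] <- stage("extract_communities",
                                extract_communities(g,
                                  method = config$community_method))
    mixing[[grp]] <- stage("genus_mixing", genus_mixing(g))
  }

  phen <- phenotype_summary(strains)
  corr <- list(
    cds_vs_genome_size = correlate(strains$n_cds, strains$genome_size),
    hgt_vs_genome_size = correlate(strains$n_hgt_cds, strains$genome_size),
    hgt_vs_cds = correlate(strains$n_hgt_cds, strains$n_cds))

  report <- list(
    provenance = list(
      package_version = as.character(utils::packageVersion("gecscan")),
      seed = config$seed,
      config_hash = config_hash(config),
      simulated = !is.null(config$simulate)),
    strains = list(n = nrow(strains),
                   mean_sugar_utilization = su_stats$mean,
                   sd_sugar_utilization = su_stats$sd),
    phenotypes = stats::setNames(as.list(phen$percent), phen$feature),
    correlations = corr,
    pangenome = list(n_clusters_total = length(clusters),
                     n_singletons_dropped = length(clusters) - length(nonsingleton),
                     n_core = length(partition$core),
                     n_accessory = length(partition$accessory),
                     n_core_percent = partition$n_percent),
    asu = list(thresholds = list(generalist_above = attr(asu, "upper"),
                                 specialist_below = attr(asu, "lower")),
               group_counts = as.list(table(asu$group)),
               group_mean_support = as.list(scatter$group_mean_support)),
    regression = lapply(regressions, function(f) list(
      r_squared = f$r_squared, r = f$r,
      coefficients = as.list(f$coefficients),
      p_values = as.list(f$p_values))),
    networks = lapply(c(generalist = "generalist", specialist = "specialist"),
                      function(grp) list(
      n_edges = mixing[[grp]]$n_edges,
      fraction_cross_genus = mixing[[grp]]$fraction_cross,
      n_communities = communities[[grp]]$n,
      community_size_max = communities[[grp]]$size_max,
      community_size_min = communities[[grp]]$size_min)))

  result <- structure(list(config = config, strains = strains,
                           clusters = nonsingleton, partition = partition,
                           su_stats = su_stats, asu = asu,
                           scatter = scatter, cog_ratios = ratios,
                           cog_comparisons = comparisons,
                           regressions = regressions,
                           networks = networks, communities = communities,
                           mixing = mixing, truth = truth,
                           report = report),
                      class = "gec_run")
  if (!is.null(config$out_dir)) write_run_outputs(result, config$out_dir)
  result
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  cfg <- unclass(config)
  cfg$out_dir <- NULL
  if (!is.null(cfg$simulate)) cfg$simulate <- unclass(cfg$simulate)
  yaml::write_yaml(cfg, tmp)
  unname(tools::md5sum(tmp))
}

write_run_outputs <- function(run, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_strain_table(run$strains, file.path(dir, "strains.tsv"))
  write_tsv(data.frame(cluster_id = run$partition$core),
            file.path(dir, "core_clusters.tsv"))
  write_tsv(data.frame(cluster_id = run$partition$accessory),
            file.path(dir, "accessory_clusters.tsv"))
  write_tsv(run$partition$scan_profile, file.path(dir, "ncore_scan.tsv"))
  write_tsv(as.data.frame(run$asu), file.path(dir, "asu.tsv"))
  for (nm in names(run$cog_comparisons))
    write_tsv(run$cog_comparisons[[nm]],
              file.path(dir, sprintf("cog_comparison_%s.tsv", nm)))
  for (f in names(run$regressions)) {
    s <- summary(run$regressions[[f]])
    write_tsv(s$table, file.path(dir, sprintf("regression_%s.tsv", f)))
  }
  for (grp in names(run$networks)) {
    export_network(run$networks[[grp]],
                   file.path(dir, sprintf("network_%s.graphml", grp)),
                   format = "graphml")
    export_network(run$networks[[grp]],
                   file.path(dir, sprintf("network_%s_edges.tsv", grp)),
                   format = "edge_tsv")
    ns <- network_summary(run$networks[[grp]], run$communities[[grp]])
    write_tsv(ns$members, file.path(dir, sprintf("communities_%s.tsv", grp)))
  }
  jsonlite::write_json(run$report, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  invisible(dir)
}

#' @export
print.gec_run <- function(x, ...) {
  r <- x$report
  cat("gec_run\n")
  cat(sprintf("  strains: %d (mean SU %.3f)\n", r$strains$n,
              r$strains$mean_sugar_utilization))
  cat(sprintf("  clusters: %d after singleton filter; %d-core %d / accessory %d\n",
              r$pangenome$n_clusters_total - r$pangenome$n_singletons_dropped,
              r$pangenome$n_core_percent, r$pangenome$n_core,
              r$pangenome$n_accessory))
  gc <- r$asu$group_counts
  cat(sprintf("  ASU groups: %s\n",
              paste(sprintf("%s=%s", names(gc), unlist(gc)), collapse = ", ")))
  for (grp in names(r$networks)) {
    n <- r$networks[[grp]]
    cat(sprintf("  %s network: %d edges, %d communities, cross-genus fraction %s\n",
                grp, n$n_edges, n$n_communities,
                format(n$fraction_cross_genus, digits = 3)))
  }
  cat(sprintf("  regressions: R^2 genome_size %.3f, n_hgt_cds %.3f\n",
              r$regression$genome_size$r_squared,
              r$regression$n_hgt_cds$r_squared))
  invisible(x)
}
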