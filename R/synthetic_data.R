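#' Simulation configuration
#'
#' Defines the study conditions the synthetic generator emulates: a
#' family-like collection of genera whose strains differ in how many sugar
#' types they metabolize, with (i) planted cross-genus communities of
#' high-utilization ("generalist") strains sharing pools of ortholog
#' clusters, (ii) per-genus pools shared by low-utilization
#' ("specialist") strains, (iii) a core genome conserved in at least 97%
#' of strains, (iv) random accessory background clusters and
#' strain-specific singletons, and (v) a planted positive effect of the
#' sugar-utilization value on genome size.
#'
#' Sugar utilization is drawn on the observed 0-17 range as a
#' three-component binomial mixture (low/intermediate/high modes near
#' 1, 8 and 16.5 with weights 0.2/0.6/0.2), so that the mean +/- 1 SD
#' classification rule has clear planted margins between the modes.
#'
#' @param n_genera Number of genera.
#' @param strains_per_genus Strains per genus (single count or
#'   `c(min, max)` range).
#' @param su_distribution List describing the sugar-utilization draw:
#'   `type = "mixture"` with `weights` and binomial success
#'   probabilities `probs` (on 17 trials), or `type = "uniform"`
#'   (integer uniform on \[0, 17\]).
#' @param generalist_threshold_quantile Strains with sugar utilization
#'   above this quantile are generalist strains (and below
#'   `1 - quantile`, specialist strains).
#' @param n_planted_communities Number of planted cross-genus
#'   communities.
#' @param community_size_range `c(min, max)` strains per planted
#'   community (min >= 2).
#' @param generalist_pool_size Clusters in each community's shared pool.
#' @param specialist_pool_size Clusters in each genus's specialist pool.
#' @param community_presence Probability that a pool cluster is present
#'   in a given member strain.
#' @param background_rate Probability that a pool cluster leaks into a
#'   given non-member strain.
#' @param core_fraction Fraction of (non-singleton) clusters forming the
#'   conserved core (present in >= 97% of strains).
#' @param background_cluster_count Random accessory clusters.
#' @param n_singleton_clusters Strain-specific clusters (dropped by the
#'   singleton filter downstream).
#' @param beta_su Planted effect of sugar utilization on genome size
#'   (bp per sugar type).
#' @param intercept Baseline genome size (bp).
#' @param noise_sd Genome-size noise SD (bp).
#' @param cog_profile_core,cog_profile_accessory Named probability
#'   vectors over [cog_levels()] used to draw COG letters
#'   (`Not_assigned` means no letter).
#' @param missing_fraction Fraction of growth/oxygen phenotype cells
#'   blanked.
#' @param missing_su_fraction Fraction of sugar-utilization cells
#'   blanked.
#' @param seed Integer seed; one global RNG stream per dataset.
#' @return A list of class `gec_sim_config`.
#' @export
sim_config <- function(n_genera = 8,
                       strains_per_genus = 12,
                       su_distribution = list(type = "mixture",
                                              weights = c(0.2, 0.6, 0.2),
                                              probs = c(0.06, 0.47, 0.97)),
                       generalist_threshold_quantile = 0.8,
                       n_planted_communities = 3,
                       community_size_range = c(5, 6),
                       generalist_pool_size = 12,
                       specialist_pool_size = 8,
                       community_presence = 0.95,
                       background_rate = 0.001,
                       core_fraction = 0.12,
                       background_cluster_count = 300,
                       n_singleton_clusters = 30,
                       beta_su = 10000,
                       intercept = 2e6,
                       noise_sd = 50000,
                       cog_profile_core = NULL,
                       cog_profile_accessory = NULL,
                       missing_fraction = 0.05,
                       missing_su_fraction = 0.02,
                       seed = 1) {
  if (is.null(cog_profile_core)) {
    p <- stats::setNames(rep(0.01, length(cog_levels())), cog_levels())
    p[c("J", "L", "K", "E", "F", "O", "M")] <- c(0.18, 0.12, 0.08, 0.08,
                                                 0.06, 0.06, 0.06)
    p["Not_assigned"] <- 0.10
    cog_profile_core <- p / sum(p)
  }
  if (is.null(cog_profile_accessory)) {
    p <- stats::setNames(rep(0.01, length(cog_levels())), cog_levels())
    p[c("G", "E", "K", "V", "X", "M", "P")] <- c(0.12, 0.08, 0.08, 0.05,
                                                 0.04, 0.04, 0.04)
    p["Not_assigned"] <- 0.30
    cog_profile_accessory <- p / sum(p)
  }
  cfg <- list(n_genera = n_genera, strains_per_genus = strains_per_genus,
              su_distribution = su_distribution,
              generalist_threshold_quantile = generalist_threshold_quantile,
              n_planted_communities = n_planted_communities,
              community_size_range = community_size_range,
              generalist_pool_size = generalist_pool_size,
              specialist_pool_size = specialist_pool_size,
              community_presence = community_presence,
              background_rate = background_rate,
              core_fraction = core_fraction,
              background_cluster_count = background_cluster_count,
              n_singleton_clusters = n_singleton_clusters,
              beta_su = beta_su, intercept = intercept, noise_sd = noise_sd,
              cog_profile_core = cog_profile_core,
              cog_profile_accessory = cog_profile_accessory,
              missing_fraction = missing_fraction,
              missing_su_fraction = missing_su_fraction,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "gec_sim_config")
}

validate_sim_config <- function(cfg) {
  counts <- c("n_genera", "generalist_pool_size", "specialist_pool_size",
              "background_cluster_count")
  for (f in counts) if (cfg[[f]] < 1) abort("%s must be positive", f)
  if (length(cfg$community_size_range) != 2L ||
      cfg$community_size_range[1] < 2L)
    abort("community_size_range must be c(min, max) with min >= 2")
  for (prof in c("cog_profile_core", "cog_profile_accessory")) {
    p <- cfg[[prof]]
    if (abs(sum(p) - 1) > 1e-9 || any(p < 0))
      abort("%s must be a probability vector summing to 1", prof)
  }
  if (cfg$su_distribution$type == "mixture" &&
      abs(sum(cfg$su_distribution$weights) - 1) > 1e-9)
    abort("su_distribution mixture weights must sum to 1")
  invisible(cfg)
}

draw_su <- function(n, dist) {
  if (dist$type == "uniform") return(sample(0:17, n, replace = TRUE))
  comp <- sample(seq_along(dist$weights), n, replace = TRUE,
                 prob = dist$weights)
  stats::rbinom(n, 17, dist$probs[comp])
}

#' Generate a seeded synthetic dataset with known ground truth
#'
#' Produces the three tables the pipeline consumes (strain table,
#' ortholog clusters with COG annotation, cluster-to-COG map) together
#' with the planted ground truth. Identical seeds give identical
#' datasets; the caller's RNG state is untouched.
#'
#' @param config A [sim_config()] object.
#' @return List with `strains` (data.frame), `clusters`
#'   ([gec_clusters], COG-annotated), `cog_map` (data.frame), and
#'   `truth` (list: `planted_generalist_clusters`,
#'   `planted_specialist_clusters`, `planted_communities`,
#'   `generalist_strains`, `specialist_strains`, `true_beta`).
#' @export
simulate_gec_dataset <- function(config = sim_config()) {
  validate_sim_config(config)
  with_seed(config$seed, simulate_gec_dataset_impl(config))
}

simulate_gec_dataset_impl <- function(cfg) {
  spg <- cfg$strains_per_genus
  per_genus <- if (length(spg) == 2L)
    sample(spg[1]:spg[2], cfg$n_genera, replace = TRUE)
  else rep(spg, cfg$n_genera)
  genus_names <- sprintf("Genus%02d", seq_len(cfg$n_genera))
  genus <- rep(genus_names, per_genus)
  n <- length(genus)
  strain_id <- sprintf("%s_s%02d", genus,
                       unlist(lapply(per_genus, seq_len)))
  su <- draw_su(n, cfg$su_distribution)
  names(su) <- strain_id

  # top/bottom (1-q) fraction of strains by sugar utilization; ties broken
  # at random (within the seeded stream) so no genus is favoured, and the
  # set sizes stay deterministic
  k <- max(2L, round(n * (1 - cfg$generalist_threshold_quantile)))
  ord <- order(-su, sample(n))
  generalist_strains <- strain_id[ord[seq_len(k)]]
  specialist_strains <- strain_id[rev(ord)[seq_len(k)]]

  # --- planted cross-genus communities of generalist strains ---
  communities <- list()
  if (cfg$n_planted_communities > 0) {
    sizes <- sample(cfg$community_size_range[1]:cfg$community_size_range[2],
                    cfg$n_planted_communities, replace = TRUE)
    if (sum(sizes) > length(generalist_strains))
      abort(paste0("infeasible config: planted communities need %d strains ",
                   "but only %d generalist strains are available"),
            sum(sizes), length(generalist_strains))
    genus_of <- function(s) genus[match(s, strain_id)]
    pool <- sample(generalist_strains)
    cand <- vector("list", length(sizes))
    off <- 0L
    for (kk in seq_along(sizes)) {
      cand[[kk]] <- pool[(off + 1):(off + sizes[kk])]
      off <- off + sizes[kk]
    }
    leftover <- pool[seq_len(length(pool) - off) + off]
    # every planted community must span >= 2 genera: swap a member with a
    # generalist of another genus (from the leftovers or another community)
    for (kk in seq_along(cand)) {
      if (length(unique(genus_of(cand[[kk]]))) >= 2L) next
      g0 <- genus_of(cand[[kk]])[1]
      swap_in <- leftover[genus_of(leftover) != g0]
      if (length(swap_in)) {
        leftover <- c(setdiff(leftover, swap_in[1]), cand[[kk]][1])
        cand[[kk]] <- c(cand[[kk]][-1], swap_in[1])
        next
      }
      donor <- which(vapply(cand, function(s)
        length(unique(genus_of(s))) >= 2L &&
          sum(genus_of(s) != g0) >= 2L, logical(1)))[1]
      if (is.na(donor))
        abort("infeasible config: could not form cross-genus communities (generalist strains span too few genera)")
      take <- cand[[donor]][genus_of(cand[[donor]]) != g0][1]
      cand[[donor]] <- c(setdiff(cand[[donor]], take), cand[[kk]][1])
      cand[[kk]] <- c(cand[[kk]][-1], take)
    }
    communities <- lapply(cand, sort)
  }

  # --- cluster construction ---
  ids <- character(0); members <- list(); origin <- character(0)
  add_cluster <- function(id, strains_in, orig) {
    if (!length(strains_in)) return(invisible(NULL))
    genes <- paste0(strains_in, "_", id)
    members[[length(members) + 1L]] <<- data.frame(
      strain_id = strains_in, gene_id = genes, stringsAsFactors = FALSE)
    ids <<- c(ids, id); origin <<- c(origin, orig)
    invisible(NULL)
  }
  pool_members <- function(core_set, presence, leak_rate) {
    present <- core_set[stats::runif(length(core_set)) < presence]
    if (length(present) < 2L) present <- core_set[1:min(2L, length(core_set))]
    others <- setdiff(strain_id, core_set)
    leak <- others[stats::runif(length(others)) < leak_rate]
    sort(c(present, leak))
  }

  for (k in seq_along(communities))
    for (j in seq_len(cfg$generalist_pool_size))
      add_cluster(sprintf("OGgen_c%02d_%03d", k, j),
                  pool_members(communities[[k]], cfg$community_presence,
                               cfg$background_rate),
                  "generalist")

  spec_by_genus <- split(specialist_strains,
                         genus[match(specialist_strains, strain_id)])
  spec_by_genus <- spec_by_genus[vapply(spec_by_genus, length, integer(1)) >= 2L]
  for (gname in names(spec_by_genus))
    for (j in seq_len(cfg$specialist_pool_size))
      add_cluster(sprintf("OGspe_%s_%03d", gname, j),
                  pool_members(spec_by_genus[[gname]], cfg$community_presence,
                               cfg$background_rate),
                  "specialist")

  n_other <- cfg$n_planted_communities * cfg$generalist_pool_size +
    length(spec_by_genus) * cfg$specialist_pool_size +
    cfg$background_cluster_count
  n_core <- max(1L, round(cfg$core_fraction / (1 - cfg$core_fraction) * n_other))
  min_core_support <- ceiling(0.97 * n)
  for (j in seq_len(n_core)) {
    supp <- sample(min_core_support:n, 1)
    add_cluster(sprintf("OGcore_%04d", j), sort(sample(strain_id, supp)),
                "core")
  }

  for (j in seq_len(cfg$background_cluster_count)) {
    supp <- sample(2:8, 1)
    add_cluster(sprintf("OGbg_%04d", j), sort(sample(strain_id, supp)),
                "background")
  }

  for (j in seq_len(cfg$n_singleton_clusters))
    add_cluster(sprintf("OGsing_%04d", j), sample(strain_id, 1), "singleton")

  clusters <- gec_clusters(ids, members)

  # --- COG assignment ---
  draw_cog <- function(profile) {
    lv <- sample(cog_levels(), 1, prob = profile)
    if (lv == "Not_assigned") return("")
    if (stats::runif(1) < 0.05) {
      extra <- sample(setdiff(cog_alphabet(), lv), 1)
      return(paste0(lv, extra))
    }
    lv
  }
  cogs <- vapply(origin, function(o)
    draw_cog(if (o == "core") cfg$cog_profile_core
             else cfg$cog_profile_accessory), character(1))
  cog_map <- data.frame(cluster_id = ids, cog = cogs,
                        stringsAsFactors = FALSE)[nzchar(cogs), ]
  rownames(cog_map) <- NULL
  clusters <- annotate_cogs(clusters, cog_map)

  # --- strain features: planted genome-size effect of sugar utilization ---
  genome_size <- round(cfg$intercept + cfg$beta_su * su +
                         stats::rnorm(n, 0, cfg$noise_sd))
  genome_size <- pmax(genome_size, 1e6)
  n_cds <- as.integer(round(genome_size / 1000) + (seq_len(n) %% 7L))
  n_hgt <- as.integer(pmin(n_cds,
                           17L + round(8 * su) + stats::rpois(n, 20)))
  growth_15C <- stats::runif(n) < 0.568
  growth_45C <- stats::runif(n) < 0.333
  oxygen <- sample(oxygen_classes(), n, replace = TRUE,
                   prob = c(0.083, 0.819, 0.098))
  # every oxygen class occurs in the family; guarantee representation so
  # the class dummies never collapse to constants
  for (cls in oxygen_classes()) {
    if (!cls %in% oxygen) {
      majority <- names(which.max(table(oxygen)))
      oxygen[sample(which(oxygen == majority), 1)] <- cls
    }
  }
  sources <- c("dairy", "vegetable", "brewing", "intestinal", "meat",
               "cereal")
  strains <- data.frame(
    strain_id = strain_id, genus = genus,
    species = paste0(tolower(genus), "_sp", ave(seq_len(n), genus,
                                                FUN = seq_along)),
    sugar_utilization = as.numeric(su),
    growth_15C = growth_15C, growth_45C = growth_45C,
    oxygen_class = oxygen,
    genome_size = genome_size, n_cds = n_cds, n_hgt_cds = n_hgt,
    gc_content = round(stats::runif(n, 0.33, 0.52), 4),
    n_rrna = sample(3:9, n, replace = TRUE),
    n_trna = sample(50:80, n, replace = TRUE),
    n_crispr = stats::rpois(n, 1.5),
    isolation_source = sample(sources, n, replace = TRUE),
    stringsAsFactors = FALSE)

  blank <- function(v, frac) {
    v[stats::runif(length(v)) < frac] <- NA
    v
  }
  strains$growth_15C <- blank(strains$growth_15C, cfg$missing_fraction)
  strains$growth_45C <- blank(strains$growth_45C, cfg$missing_fraction)
  strains$oxygen_class <- blank(strains$oxygen_class, cfg$missing_fraction)
  strains$sugar_utilization <- blank(strains$sugar_utilization,
                                     cfg$missing_su_fraction)

  truth <- list(
    planted_generalist_clusters = ids[origin == "generalist"],
    planted_specialist_clusters = ids[origin == "specialist"],
    planted_core_clusters = ids[origin == "core"],
    planted_communities = communities,
    generalist_strains = sort(generalist_strains),
    specialist_strains = sort(specialist_strains),
    true_beta = c(sugar_utilization = cfg$beta_su),
    seed = cfg$seed)

  list(strains = strains, clusters = clusters, cog_map = cog_map,
       truth = truth, config = cfg)
}

#' Write a simulated dataset to disk
#'
#' Emits exactly the three TSV inputs the loaders consume
#' (`strains.tsv`, `ortholog_groups.tsv`, `cog_map.tsv`) plus the ground
#' truth as `ground_truth.yaml`.
#'
#' @param dataset Result of [simulate_gec_dataset()] or
#'   [make_toy_fixture()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_gec_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_strain_table(dataset$strains, file.path(dir, "strains.tsv"))
  write_ortholog_groups(dataset$clusters, file.path(dir, "ortholog_groups.tsv"),
                        strains = dataset$strains$strain_id)
  write_tsv(dataset$cog_map, file.path(dir, "cog_map.tsv"))
  if (!is.null(dataset$truth))
    yaml::write_yaml(dataset$truth, file.path(dir, "ground_truth.yaml"))
  invisible(dir)
}

#' Hand-sized toy dataset with hand-checkable statistics
#'
#' A deterministic 12-strain, 24-cluster fixture over two genera with one
#' planted cross-genus community of four strains sharing seven
#' generalist-pool clusters, two per-genus specialist pools, five core
#' clusters, two strain-specific singletons and three background
#' clusters. The strain sugar-utilization values give mean 97/12 and
#' sample SD 5.5671, so the classification thresholds are hand-checkable
#' (generalist > 13.6504, specialist < 2.5162); cluster `OG_gen1` has
#' members with sugar values \{10, 14, 15\}, hence ASU exactly 13.0.
#'
#' @return Same structure as [simulate_gec_dataset()].
#' @export
make_toy_fixture <- function() {
  su <- c(1, 2, 8, 7, 10, 14, 15, 12, 16, 1, 2, 9)
  ids <- c(paste0("a", 1:6), paste0("b", 1:6))
  genus <- rep(c("Lactobacillus", "Lacticaseibacillus"), each = 6)
  genome_size <- 2e6 + 10000 * su
  strains <- data.frame(
    strain_id = ids, genus = genus,
    species = paste0(tolower(genus), "_sp", rep(1:6, 2)),
    sugar_utilization = su,
    growth_15C = su >= 7,
    growth_45C = c(rep(FALSE, 4), TRUE, TRUE, TRUE, FALSE, TRUE,
                   FALSE, FALSE, NA),
    oxygen_class = c("microaerobic", "obligate_anaerobic",
                     "facultatively_anaerobic", NA,
                     rep("facultatively_anaerobic", 6),
                     "obligate_anaerobic", "facultatively_anaerobic"),
    genome_size = genome_size,
    n_cds = as.integer(round(genome_size / 1000)),
    n_hgt_cds = as.integer(20 + 8 * su),
    gc_content = round(seq(0.36, 0.47, length.out = 12), 4),
    n_rrna = rep(c(4L, 5L, 6L), 4),
    n_trna = rep(c(55L, 60L, 65L, 70L), 3),
    n_crispr = rep(c(0L, 1L, 2L), 4),
    isolation_source = rep(c("dairy", "vegetable", "brewing"), 4),
    stringsAsFactors = FALSE)

  comm <- c("a6", "b1", "b2", "b3") # SU 14, 15, 12, 16 -> ASU 14.25
  supports <- list(
    OG_gen1 = c("a5", "a6", "b1"), # SU 10, 14, 15 -> ASU 13.0
    OG_gen2 = comm, OG_gen3 = comm, OG_gen4 = comm, OG_gen5 = comm,
    OG_gen6 = comm, OG_gen7 = comm, OG_gen8 = comm,
    OG_speA1 = c("a1", "a2"), OG_speA2 = c("a1", "a2"),
    OG_speA3 = c("a1", "a2"),
    OG_speB1 = c("b4", "b5"), OG_speB2 = c("b4", "b5"),
    OG_speB3 = c("b4", "b5"),
    OG_core1 = ids, OG_core2 = ids, OG_core3 = ids, OG_core4 = ids,
    OG_core5 = ids,
    OG_sing1 = "a3", OG_sing2 = "b6",
    OG_bg1 = c("a3", "a4", "b6"), OG_bg2 = c("a4", "b6"),
    OG_bg3 = c("a3", "b6"))
  members <- lapply(names(supports), function(id) {
    s <- supports[[id]]
    m <- data.frame(strain_id = s, gene_id = paste0(s, "_", id),
                    stringsAsFactors = FALSE)
    if (id == "OG_sing1") # in-paralog pair: still strain-specific
      m <- rbind(m, data.frame(strain_id = "a3", gene_id = "a3_OG_sing1b"))
    m
  })
  clusters <- gec_clusters(names(supports), members)
  cog_map <- data.frame(
    cluster_id = c("OG_gen1", "OG_gen2", "OG_gen3", "OG_gen4", "OG_gen5",
                   "OG_gen6", "OG_gen8",
                   "OG_speA1", "OG_speA3", "OG_speB1", "OG_speB3",
                   "OG_core1", "OG_core2", "OG_core3", "OG_core4",
                   "OG_core5", "OG_sing2", "OG_bg1", "OG_bg3"),
    cog = c("G", "G", "E", "GE", "V", "K", "G",
            "G", "E", "K", "P",
            "J", "J", "L", "K", "E", "S", "R", "S"),
    stringsAsFactors = FALSE)
  clusters <- annotate_cogs(clusters, cog_map)
  truth <- list(
    planted_generalist_clusters = paste0("OG_gen", 2:8),
    planted_specialist_clusters = c(paste0("OG_speA", 1:3),
                                    paste0("OG_speB", 1:3)),
    planted_core_clusters = paste0("OG_core", 1:5),
    planted_communities = list(comm),
    generalist_strains = sort(comm),
    specialist_strains = c("a1", "a2", "b4", "b5"),
    true_beta = c(sugar_utilization = 10000),
    seed = NA_integer_)
  list(strains = strains, clusters = clusters, cog_map = cog_map,
       truth = truth, config = NULL)
}
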