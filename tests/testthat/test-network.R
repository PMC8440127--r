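pair_strains <- function(ids, genus = rep("G", length(ids))) {
  data.frame(strain_id = ids, genus = genus,
             species = "sp", sugar_utilization = seq_along(ids),
             stringsAsFactors = FALSE)
}

shared_pool <- function(n_shared, pair = c("x", "y"), extra = "z") {
  ids <- sprintf("OG%02d", seq_len(n_shared))
  gec_clusters(ids, lapply(ids, function(id)
    data.frame(strain_id = pair, gene_id = paste0(pair, "_", id),
               stringsAsFactors = FALSE)))
}

test_that("the edge rule is strictly 'more than threshold'", {
  strains <- pair_strains(c("x", "y", "z"))
  g6 <- build_gec_network(shared_pool(6), paste0("OG0", 1:6), strains,
                          threshold = 5)
  expect_equal(igraph::ecount(g6), 1)
  expect_equal(igraph::E(g6)$shared_count, 6)
  g5 <- build_gec_network(shared_pool(5), paste0("OG0", 1:5), strains,
                          threshold = 5)
  expect_equal(igraph::ecount(g5), 0)
  expect_equal(igraph::vcount(g5), 3) # isolated nodes retained
  empty <- build_gec_network(shared_pool(6), character(0), strains)
  expect_equal(igraph::ecount(empty), 0)
  expect_error(build_gec_network(shared_pool(6), "OG01",
                                 strains[0, , drop = FALSE]), "empty strain")
})

test_that("shared counts are symmetric, monotone in threshold, and match brute force", {
  withr::with_seed(41, {
    ids <- sprintf("s%02d", 1:20)
    strains <- pair_strains(ids, genus = sample(LETTERS[1:4], 20,
                                                replace = TRUE))
    cl <- random_clusters(200, ids, with_cogs = FALSE)
    pick <- sample(cl$cluster_id, 120)
    m <- shared_counts(cl, pick, ids)
    expect_true(isSymmetric(unname(m)))
    brute <- shared_oracle(cl, pick, ids)
    diag(brute) <- diag(m) # oracle leaves the diagonal at 0
    expect_equal(unname(m), unname(brute))

    edges_at <- function(t) {
      g <- build_gec_network(cl, pick, strains, threshold = t)
      e <- igraph::as_data_frame(g, what = "edges")
      sort(paste(pmin(e$from, e$to), pmax(e$from, e$to)))
    }
    e5 <- edges_at(5); e10 <- edges_at(10); e20 <- edges_at(20)
    expect_true(all(e10 %in% e5))
    expect_true(all(e20 %in% e10))
  })
})

test_that("components extraction drops singletons and summarizes sizes", {
  g <- igraph::graph_from_data_frame(
    data.frame(from = c("a", "b", "d"), to = c("b", "c", "e")),
    directed = FALSE,
    vertices = data.frame(name = c("a", "b", "c", "d", "e", "f"),
                          genus = c("G1", "G1", "G1", "G2", "G2", "G3")))
  comm <- extract_communities(g)
  expect_equal(comm$n, 2)
  expect_equal(comm$size_max, 3)
  expect_equal(comm$size_min, 2)
  expect_equal(comm$communities[[1]], c("a", "b", "c"))
  expect_equal(comm$communities[[2]], c("d", "e"))

  ns <- network_summary(g, comm)
  expect_equal(ns$n_communities, 2)
  expect_equal(nrow(ns$members), 5)
  expect_equal(ns$members$genus[ns$members$strain_id == "d"], "G2")

  edgeless <- igraph::delete_edges(g, igraph::E(g))
  comm0 <- extract_communities(edgeless)
  expect_equal(comm0$n, 0)
  expect_true(is.na(comm0$size_max))
  ns0 <- network_summary(edgeless, comm0)
  expect_equal(nrow(ns0$members), 0)

  greedy <- extract_communities(g, method = "greedy_modularity")
  expect_equal(greedy$n, 2)
})

test_that("genus mixing separates within- from cross-genus edges", {
  v <- data.frame(name = c("a", "b", "c", "d"),
                  genus = c("G1", "G1", "G2", "G3"))
  same <- igraph::graph_from_data_frame(
    data.frame(from = "a", to = "b"), directed = FALSE, vertices = v)
  mx <- genus_mixing(same)
  expect_equal(mx$fraction_cross, 0)
  expect_setequal(mx$genera_without_edges, c("G2", "G3"))

  cross <- igraph::graph_from_data_frame(
    data.frame(from = "a", to = "c"), directed = FALSE, vertices = v)
  expect_equal(genus_mixing(cross)$fraction_cross, 1)

  none <- igraph::delete_edges(same, igraph::E(same))
  expect_true(is.na(genus_mixing(none)$fraction_cross))
})

test_that("adjusted Rand index scores community recovery", {
  truth <- list(c("a", "b", "c"), c("d", "e"))
  expect_equal(community_ari(truth, truth,
                             strains = c("a", "b", "c", "d", "e", "f")), 1)
  wrong <- list(c("a", "d"), c("b", "e"))
  expect_lt(community_ari(wrong, truth,
                          strains = c("a", "b", "c", "d", "e", "f")), 0.5)
})

test_that("planted cross-genus structure shows up in the mixing report", {
  d <- simulate_gec_dataset(sim_config(seed = 19))
  cl <- suppressMessages(drop_singletons(d$clusters))
  asu <- classify_clusters(compute_asu(cl, d$strains),
                           strain_su_stats(d$strains))
  gen_g <- build_gec_network(cl, asu$cluster_id[asu$group == "generalist"],
                             d$strains, threshold = 5, group = "generalist")
  spe_g <- build_gec_network(cl, asu$cluster_id[asu$group == "specialist"],
                             d$strains, threshold = 5, group = "specialist")
  expect_gt(genus_mixing(gen_g)$fraction_cross, 0)
  mx <- genus_mixing(spe_g)
  expect_gt(mx$n_edges, 0)
  expect_equal(mx$fraction_cross, 0)
})
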