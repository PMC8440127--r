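cog_set <- function(cogs) {
  ids <- sprintf("OG%02d", seq_along(cogs))
  cl <- gec_clusters(ids, lapply(ids, function(id)
    data.frame(strain_id = c("s1", "s2"), gene_id = paste0(c("s1", "s2"), id),
               stringsAsFactors = FALSE)))
  cl$cog <- cogs
  cl
}

test_that("COG ratios split multi-letter clusters and normalize to 1", {
  cl <- cog_set(list("G", "G", "E", character(0)))
  r <- cog_ratios(cl)
  expect_equal(unname(r["G"]), 0.5)
  expect_equal(unname(r["E"]), 0.25)
  expect_equal(unname(r["Not_assigned"]), 0.25)

  r2 <- cog_ratios(cog_set(list(c("G", "E"))))
  expect_equal(unname(r2["G"]), 0.5)
  expect_equal(unname(r2["E"]), 0.5)

  # count-each weighting counts every letter once
  r3 <- cog_ratios(cog_set(list(c("G", "E"), "G")), weighting = "count_each")
  expect_equal(unname(r3["G"]), 2 / 3)

  withr::with_seed(5, {
    cl4 <- random_clusters(30, c("s1", "s2", "s3"))
    expect_equal(sum(cog_ratios(cl4)), 1)
    # adding a cluster with category G never decreases ratio(G)
    base_r <- cog_ratios(cl4, cl4$cluster_id[1:20])
    grown <- cl4
    grown$cluster_id <- c(grown$cluster_id, "EXTRA")
    grown$members <- c(grown$members, list(data.frame(
      strain_id = c("s1", "s2"), gene_id = c("x1", "x2"))))
    grown$cog <- c(grown$cog, list("G"))
    grown_r <- cog_ratios(grown, c(cl4$cluster_id[1:20], "EXTRA"))
    expect_gte(grown_r["G"], base_r["G"])
  })
  expect_error(cog_ratios(cl, character(0)), "empty")
})

test_that("per-category comparisons match an independent Welch computation", {
  # category absent from both sets -> ND
  cl <- cog_set(list("J", "J", "K", "K"))
  expect_true(is.na(compare_cog_category(cl, cl$cluster_id[1:2],
                                         cl$cluster_id[3:4], "B")))
  # hand-computed worked vectors: a = (1,1,0,0,0), b = (0,...,0,1)
  cl2 <- cog_set(list("G", "G", "J", "J", "J",
                      "J", "J", "J", "J", "J", "J", "J", "G"))
  a_ids <- cl2$cluster_id[1:5]
  b_ids <- cl2$cluster_id[6:13]
  p <- compare_cog_category(cl2, a_ids, b_ids, "G")
  expect_equal(p, welch_oracle(c(1, 1, 0, 0, 0), c(0, 0, 0, 0, 0, 0, 0, 1)),
               tolerance = 1e-12)

  # identical non-degenerate indicator distributions -> p = 1
  cl3 <- cog_set(list("G", "J", "G", "J"))
  expect_equal(compare_cog_category(cl3, cl3$cluster_id[1:2],
                                    cl3$cluster_id[3:4], "G"), 1)

  # both vectors constant with equal means -> degenerate -> ND
  cl4 <- cog_set(list("G", "G", "G", "G"))
  expect_true(is.na(compare_cog_category(cl4, cl4$cluster_id[1:2],
                                         cl4$cluster_id[3:4], "G")))

  # random indicator vectors agree with the oracle to 1e-10
  withr::with_seed(13, {
    for (rep in 1:20) {
      na <- sample(3:12, 1); nb <- sample(3:12, 1)
      cogs <- c(lapply(runif(na) < 0.4, function(x) if (x) "G" else "J"),
                lapply(runif(nb) < 0.6, function(x) if (x) "G" else "J"))
      cl5 <- cog_set(cogs)
      a <- vapply(cogs[1:na], function(x) as.numeric(x == "G"), numeric(1))
      b <- vapply(cogs[(na + 1):(na + nb)], function(x) as.numeric(x == "G"),
                  numeric(1))
      if (var(a) == 0 && var(b) == 0) next
      expect_equal(compare_cog_category(cl5, cl5$cluster_id[1:na],
                                        cl5$cluster_id[(na + 1):(na + nb)],
                                        "G"),
                   welch_oracle(a, b), tolerance = 1e-10)
      expect_equal(compare_cog_category(cl5, cl5$cluster_id[1:na],
                                        cl5$cluster_id[(na + 1):(na + nb)],
                                        "G", var_equal = TRUE),
                   student_oracle(a, b), tolerance = 1e-10)
    }
  })
})

test_that("BH correction matches the exhaustive step-up oracle", {
  expect_equal(unname(bh_correct(c(0.001, 0.01, 0.02, 0.04))),
               rep(TRUE, 4)) # p(4) = 0.04 <= 0.05
  expect_equal(unname(bh_correct(rep(1, 5))), rep(FALSE, 5))
  mixed <- bh_correct(c(0.01, NA, 0.5))
  expect_true(is.na(mixed[2])) # ND propagates

  withr::with_seed(17, {
    for (rep in 1:1000) {
      m <- sample(1:30, 1)
      p <- round(runif(m)^sample(1:3, 1), 4)
      if (runif(1) < 0.3) p[sample(m, min(m, 2))] <- NA
      alpha <- sample(c(0.01, 0.05, 0.1), 1)
      expect_identical(unname(bh_correct(p, alpha)), bh_oracle(p, alpha))
    }
  })
})

test_that("phenotype percentages use per-feature denominators", {
  strains <- data.frame(
    strain_id = paste0("s", 1:4), genus = "G", species = "sp",
    sugar_utilization = 1:4,
    growth_15C = c(TRUE, TRUE, FALSE, NA),
    growth_45C = c(NA, NA, NA, NA),
    oxygen_class = c("microaerobic", "facultatively_anaerobic",
                     "facultatively_anaerobic", NA),
    stringsAsFactors = FALSE)
  ps <- phenotype_summary(strains)
  g15 <- ps[ps$feature == "growth_15C", ]
  expect_equal(g15$percent, 100 * 2 / 3, tolerance = 1e-12)
  expect_equal(g15$denominator, 3)
  g45 <- ps[ps$feature == "growth_45C", ]
  expect_true(is.na(g45$percent))
  expect_equal(g45$denominator, 0)
  fan <- ps[ps$feature == "facultatively_anaerobic", ]
  expect_equal(fan$percent, 100 * 2 / 3, tolerance = 1e-12)
})

test_that("correlation handles exact linearity and missing pairs", {
  x <- 1:10
  expect_equal(correlate(x, 2 * x + 1), 1)
  expect_equal(correlate(c(1, 2, 3), c(3, 2, 1)), -1)
  expect_error(correlate(c(1, 2, 3), c(5, 5, 5)), "zero variance")
  expect_error(correlate(1:2, 1:3), "equal length")
  # pairwise-complete deletion
  x2 <- c(1, 2, 3, 4, NA)
  y2 <- c(2, 4, 6, NA, 10)
  expect_equal(correlate(x2, y2), 1)
  expect_error(correlate(c(1, 2, NA), c(1, 2, 3)), "complete pairs")
})
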