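strains_with_su <- function(su, ids = sprintf("s%02d", seq_along(su))) {
  data.frame(strain_id = ids, genus = "G", species = "sp",
             sugar_utilization = su, stringsAsFactors = FALSE)
}

clusters_over <- function(supports) {
  gec_clusters(names(supports), lapply(names(supports), function(id) {
    s <- supports[[id]]
    data.frame(strain_id = s, gene_id = paste0(s, "_", id),
               stringsAsFactors = FALSE)
  }))
}

test_that("strain-level sugar statistics use sample SD and exclusion", {
  st <- strain_su_stats(strains_with_su(c(4, 10)))
  expect_equal(st$mean, 7)
  expect_equal(st$sd, sqrt(18)) # ~4.2426
  expect_equal(strain_su_stats(strains_with_su(c(5, 5, 5)))$sd, 0)
  st2 <- strain_su_stats(strains_with_su(c(4, 10, NA)))
  expect_equal(st2$n_strains_used, 2)
  expect_equal(st2$n_missing, 1)
  expect_error(strain_su_stats(strains_with_su(c(4, NA))), ">= 2 strains")
})

test_that("ASU averages distinct support strains, excluding missing values", {
  strains <- strains_with_su(c(10, 14, 15, 8, NA), c("p", "q", "r", "s", "t"))
  cl <- clusters_over(list(OGa = c("p", "q", "r"),
                           OGb = c("s", "t"),
                           OGc = "t"))
  # a strain with two gene copies still counts once
  cl$members[[1]] <- rbind(cl$members[[1]],
                           data.frame(strain_id = "p", gene_id = "p_dup"))
  asu <- compute_asu(cl, strains)
  expect_equal(asu$asu[1], 13.0)
  expect_equal(asu$n_strains[1], 3)
  expect_equal(asu$asu[2], 8.0)
  expect_equal(asu$n_strains_with_su[2], 1)
  expect_true(is.na(asu$asu[3]))
  expect_equal(asu$group[3], "unclassifiable")

  imputed <- compute_asu(cl, strains, impute = "global_mean")
  expect_equal(imputed$asu[2], mean(c(8, mean(c(10, 14, 15, 8)))))
})

test_that("classification applies strict mean +/- 1 SD thresholds", {
  asu <- compute_asu(clusters_over(list(hi = c("a", "b"), lo = c("c", "d"),
                                        tie = c("e", "f"))),
                     strains_with_su(c(11, 11, 5, 5, 10, 10),
                                     c("a", "b", "c", "d", "e", "f")))
  st <- structure(list(mean = 6.83, sd = 4.0, n_strains_used = 6,
                       n_missing = 0), class = "gec_su_stats")
  out <- classify_clusters(asu, st)
  expect_equal(out$group[out$cluster_id == "hi"], "generalist") # 11 > 10.83
  # with mean 6.83, sd 4 the lower threshold is 2.83, so 5 is intermediate
  expect_equal(out$group[out$cluster_id == "lo"], "intermediate")

  st2 <- structure(list(mean = 8, sd = 2, n_strains_used = 6, n_missing = 0),
                   class = "gec_su_stats")
  out2 <- classify_clusters(asu, st2)
  expect_equal(out2$group[out2$cluster_id == "lo"], "specialist") # 5 < 6
  expect_equal(out2$group[out2$cluster_id == "tie"], "intermediate") # 10 = 8+2

  st0 <- structure(list(mean = 5, sd = 0, n_strains_used = 6, n_missing = 0),
                   class = "gec_su_stats")
  expect_error(classify_clusters(asu, st0), "sd is 0")
})

test_that("ASU bounds, partition completeness and order invariance hold", {
  withr::with_seed(31, {
    for (rep in 1:5) {
      ids <- sprintf("s%02d", 1:15)
      su <- sample(0:17, 15, replace = TRUE)
      su[sample(15, 2)] <- NA
      strains <- strains_with_su(su, ids)
      cl <- random_clusters(40, ids, with_cogs = FALSE)
      asu <- compute_asu(cl, strains)
      st <- strain_su_stats(strains)
      asu <- classify_clusters(asu, st)

      for (i in seq_len(nrow(asu))) {
        vals <- su[match(cluster_support(cl)[[i]], ids)]
        vals <- vals[!is.na(vals)]
        if (length(vals)) {
          expect_gte(asu$asu[i], min(vals))
          expect_lte(asu$asu[i], max(vals))
        } else {
          expect_equal(asu$group[i], "unclassifiable")
        }
      }
      expect_equal(sum(table(asu$group)), length(cl))

      # permuting cluster and strain-row order changes nothing
      perm_cl <- cl[sample(length(cl))]
      perm_strains <- strains[sample(nrow(strains)), ]
      asu2 <- classify_clusters(compute_asu(perm_cl, perm_strains),
                                strain_su_stats(perm_strains))
      reord <- asu2[match(asu$cluster_id, asu2$cluster_id), ]
      rownames(reord) <- NULL
      expect_equal(reord$asu, asu$asu)
      expect_equal(reord$group, asu$group)
    }
  })
})

test_that("scatter summary reports support by group without crashing on gaps", {
  asu <- compute_asu(clusters_over(list(a = c("p", "q"), b = c("q", "r"),
                                        c = c("p", "r"))),
                     strains_with_su(c(3, 9, 15), c("p", "q", "r")))
  sc <- asu_scatter_summary(classify_clusters(asu, structure(
    list(mean = 9, sd = 3, n_strains_used = 3, n_missing = 0),
    class = "gec_su_stats")))
  expect_equal(nrow(sc$points), 3)
  expect_true(is.na(sc$group_mean_support["generalist"])) # none above 12
  expect_equal(sum(sc$asu_hist$count), 3)

  toy <- make_toy_fixture()
  cl <- suppressMessages(drop_singletons(toy$clusters))
  classified <- classify_clusters(compute_asu(cl, toy$strains),
                                  strain_su_stats(toy$strains))
  sc2 <- asu_scatter_summary(classified)
  expect_gt(sc2$group_mean_support["generalist"],
            sc2$group_mean_support["specialist"])
})
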