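fake_strains <- function(n, seed = 1) {
  withr::with_seed(seed, data.frame(
    strain_id = sprintf("s%04d", 1:n), genus = "G", species = "sp",
    sugar_utilization = sample(0:17, n, replace = TRUE),
    growth_15C = runif(n) < 0.5,
    growth_45C = runif(n) < 0.4,
    oxygen_class = sample(c("microaerobic", "facultatively_anaerobic",
                            "obligate_anaerobic"), n, replace = TRUE),
    genome_size = 2e6 + rnorm(n, 0, 5e4),
    n_cds = 2000 + rpois(n, 50),
    n_hgt_cds = 100 + rpois(n, 10),
    gc_content = runif(n, 0.3, 0.5),
    n_rrna = sample(3:9, n, replace = TRUE),
    n_trna = sample(50:80, n, replace = TRUE),
    n_crispr = rpois(n, 1.5),
    stringsAsFactors = FALSE))
}

test_that("design building imputes means then Z-scores every predictor", {
  strains <- fake_strains(50)
  strains$growth_15C[c(3, 9)] <- NA
  strains$oxygen_class[5] <- NA
  d <- build_design(strains)
  expect_equal(colnames(d$X),
               c("sugar_utilization", "growth_15C", "growth_45C",
                 "microaerobic", "facultatively_anaerobic",
                 "obligate_anaerobic", "gc_content", "n_rrna", "n_trna",
                 "n_crispr"))
  expect_true(all(abs(colMeans(d$X)) < 1e-9))
  expect_equal(unname(apply(d$X, 2, sd)), rep(1, 10))
  expect_equal(unname(d$imputed["growth_15C"]), 2L)
  expect_equal(unname(d$imputed["microaerobic"]), 1L)
  # the imputed cell equals the observed mean, i.e. z-score 0 pre-rounding
  raw_mean <- mean(strains$growth_15C, na.rm = TRUE)
  expect_equal(unname(d$X[3, "growth_15C"] * d$scale["growth_15C"] +
                        d$center["growth_15C"]), raw_mean)

  strains$n_crispr <- 0L
  expect_error(build_design(strains), "n_crispr")
  strains$n_crispr <- NA_integer_
  expect_error(build_design(strains), "entirely missing")
})

test_that("OLS matches the normal equations and is scale equivariant", {
  withr::with_seed(23, {
    for (rep in 1:5) {
      n <- sample(8:10, 1); p <- sample(2:6, 1)
      X <- matrix(rnorm(n * p), n, p,
                  dimnames = list(NULL, paste0("x", 1:p)))
      y <- rnorm(n)
      fit <- fit_ols(X, y)
      expect_equal(unname(coef(fit)), unname(ols_oracle(X, y)),
                   tolerance = 1e-8)
      expect_equal(fit$r, sqrt(fit$r_squared), tolerance = 1e-12)
    }
  })

  # noiseless linear objective -> R^2 = 1
  X <- matrix(rnorm(60), 30, 2, dimnames = list(NULL, c("a", "b")))
  y <- 3 + 2 * X[, 1] - X[, 2]
  expect_equal(fit_ols(X, y)$r_squared, 1, tolerance = 1e-12)

  # scale equivariance through Z-scoring
  strains <- fake_strains(60, seed = 9)
  strains$oxygen_class[c(2, 8)] <- NA # breaks nothing, exercises imputation
  y <- strains$genome_size
  f1 <- fit_ols(build_design(strains), y, objective = "genome_size")
  strains2 <- strains
  strains2$gc_content <- strains2$gc_content * 100
  f2 <- fit_ols(build_design(strains2), y, objective = "genome_size")
  expect_equal(coef(f1), coef(f2), tolerance = 1e-9)
  expect_equal(f1$p_values, f2$p_values, tolerance = 1e-9)
  expect_equal(f1$r_squared, f2$r_squared, tolerance = 1e-12)
})

test_that("a null objective at n = 1000 gives near-zero R^2", {
  strains <- fake_strains(1000, seed = 4)
  withr::with_seed(5, y <- rnorm(1000))
  fit <- fit_ols(build_design(strains, drop_reference_class = TRUE), y)
  expect_lt(fit$r_squared, 0.05)
})

test_that("rank-deficient oxygen dummies are handled as documented", {
  strains <- fake_strains(40, seed = 2) # no missing classes -> exact collinearity
  d <- build_design(strains)
  expect_error(fit_ols(d, strains$genome_size, singular = "error"),
               "rank-deficient")
  fit <- fit_ols(d, strains$genome_size) # minimum-norm solution
  expect_equal(fit$rank, 10) # 11 columns, one dependency
  expect_length(coef(fit), 11)
  # fitted values agree with lm on the same (deficient) design
  lmfit <- lm(strains$genome_size ~ d$X)
  expect_equal(unname(fitted(fit)), unname(fitted(lmfit)), tolerance = 1e-8)
  expect_equal(fit$r_squared, summary(lmfit)$r.squared, tolerance = 1e-12)
  # minimum-norm: no other exact solution has smaller coefficient norm
  alt <- coef(lmfit)
  alt[is.na(alt)] <- 0
  expect_lte(sum(coef(fit)^2), sum(alt^2) + 1e-8)

  # dropping the reference class restores a full-rank fit
  full <- fit_ols(build_design(strains, drop_reference_class = TRUE),
                  strains$genome_size, singular = "error")
  expect_equal(full$rank, 10)
  expect_equal(full$r_squared, fit$r_squared, tolerance = 1e-12)
})

test_that("the planted sugar-utilization effect is recovered on synthetic data", {
  d <- simulate_gec_dataset(sim_config(seed = 27))
  fits <- run_feature_regressions(d$strains)
  gs <- fits$genome_size
  expect_gt(coef(gs)["sugar_utilization"], 0)
  expect_lte(gs$p_values["sugar_utilization"], 0.05)
  expect_true(gs$r_squared > 0 && gs$r_squared <= 1)
  hgt <- fits$n_hgt_cds
  expect_gt(coef(hgt)["sugar_utilization"], 0)
  expect_lte(hgt$p_values["sugar_utilization"], 0.05)
  s <- summary(gs)
  expect_setequal(s$table$predictor, colnames(build_design(d$strains)$X))
})
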