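# Independent brute-force oracles used to cross-check the implementation.

# Benjamini-Hochberg step-up, spelled out literally: sort ascending, find
# the largest k with p(k) <= k * alpha / m, call ranks <= k significant.
bh_oracle <- function(p, alpha = 0.05) {
  out <- rep(NA, length(p))
  def <- which(!is.na(p))
  m <- length(def)
  if (m == 0) return(out)
  ord <- def[order(p[def])]
  k_star <- 0
  for (k in seq_len(m)) {
    if (p[ord[k]] <= k * alpha / m) k_star <- k
  }
  out[def] <- FALSE
  if (k_star > 0) out[ord[seq_len(k_star)]] <- TRUE
  out
}

# Welch two-sample t-test from the textbook formulas.
welch_oracle <- function(a, b) {
  va <- var(a) / length(a)
  vb <- var(b) / length(b)
  t_stat <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  2 * pt(-abs(t_stat), df)
}

# Student pooled-variance two-sample t-test.
student_oracle <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  t_stat <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  2 * pt(-abs(t_stat), na + nb - 2)
}

# OLS by the normal equations (full-rank designs only).
ols_oracle <- function(X, y) {
  Xi <- cbind(1, X)
  drop(solve(crossprod(Xi), crossprod(Xi, y)))
}

# n-core membership by a literal per-cluster loop.
ncore_oracle <- function(pm, n_percent) {
  n <- nrow(pm)
  core <- character(0)
  for (j in seq_len(ncol(pm))) {
    if (sum(pm[, j]) / n >= n_percent / 100)
      core <- c(core, colnames(pm)[j])
  }
  core
}

# Shared-cluster counts by a double loop over strain pairs and clusters.
shared_oracle <- function(clusters, ids, strains) {
  supp <- cluster_support(clusters[ids])
  m <- matrix(0L, length(strains), length(strains),
              dimnames = list(strains, strains))
  for (i in seq_along(strains)) {
    for (j in seq_along(strains)) {
      if (i == j) next
      m[i, j] <- sum(vapply(supp, function(s)
        strains[i] %in% s && strains[j] %in% s, logical(1)))
    }
  }
  m
}

# Random cluster collection over a strain set, for property tests.
random_clusters <- function(n_clusters, strains, max_support = length(strains),
                            with_cogs = TRUE) {
  ids <- sprintf("RC%03d", seq_len(n_clusters))
  members <- lapply(ids, function(id) {
    s <- sample(strains, sample(1:max_support, 1))
    data.frame(strain_id = s, gene_id = paste0(s, "_", id),
               stringsAsFactors = FALSE)
  })
  cl <- gec_clusters(ids, members)
  if (with_cogs) {
    cl$cog <- lapply(seq_along(ids), function(i) {
      k <- sample(0:2, 1, prob = c(0.3, 0.6, 0.1))
      sample(c("J", "K", "L", "G", "E", "V", "S"), k)
    })
  }
  cl
}

toy_dir <- function() system.file("extdata", "toy", package = "gecscan")
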