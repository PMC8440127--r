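#' COG functional-category ratios of a cluster set
#'
#' Computes the proportion of a cluster set falling in each of the 26 COG
#' categories plus `Not_assigned`. Under the default `"split"` weighting
#' each cluster contributes a total weight of 1, divided equally among its
#' assigned letters (a \{G,E\} cluster adds 1/2 to G and 1/2 to E; an
#' unannotated cluster adds 1 to `Not_assigned`), so the ratios sum to 1
#' and stacked-bar profiles are well formed. The `"count_each"` weighting
#' instead counts every letter once and normalizes by the total letter
#' count.
#'
#' @param clusters A [gec_clusters] object with COG annotations.
#' @param ids Cluster ids forming the set (default: all clusters).
#' @param weighting `"split"` (default) or `"count_each"`.
#' @return Named numeric vector over [cog_levels()], with attribute
#'   `n_clusters`.
#' @export
cog_ratios <- function(clusters, ids = NULL,
                       weighting = c("split", "count_each")) {
  weighting <- match.arg(weighting)
  stopifnot(inherits(clusters, "gec_clusters"))
  if (is.null(ids)) ids <- clusters$cluster_id
  if (!length(ids)) abort("empty cluster set")
  sub <- clusters[ids]
  w <- stats::setNames(numeric(length(cog_levels())), cog_levels())
  for (cats in sub$cog) {
    if (!length(cats)) {
      w["Not_assigned"] <- w["Not_assigned"] + 1
    } else if (weighting == "split") {
      w[cats] <- w[cats] + 1 / length(cats)
    } else {
      w[cats] <- w[cats] + 1
    }
  }
  out <- w / sum(w)
  attr(out, "n_clusters") <- length(ids)
  out
}

#' Per-category indicator vectors for a cluster set
#' @noRd
cog_indicators <- function(clusters, ids, category) {
  sub <- clusters[ids]
  vapply(sub$cog, function(cats) as.numeric(category %in% cats), numeric(1))
}

#' Compare one COG category between two cluster sets (Welch t-test)
#'
#' Treats clusters as sampling units: each cluster in a set contributes an
#' indicator (1 if assigned to the category — for `"Not_assigned"`, if it
#' has no letters — else 0), and the two indicator vectors are compared
#' with a two-sample t-test (Welch by default). The test is undefined
#' ("ND", returned as `NA`) when the category is absent from both sets or
#' the data are degenerate (both vectors constant with equal means, where
#' the t statistic does not exist).
#'
#' @param clusters Annotated [gec_clusters] object.
#' @param set_a,set_b Cluster-id vectors (both non-empty).
#' @param category One COG letter or `"Not_assigned"`.
#' @param var_equal Use the pooled-variance Student test instead of Welch.
#' @return Two-sided p-value, or `NA_real_` for ND.
#' @export
compare_cog_category <- function(clusters, set_a, set_b, category,
                                 var_equal = FALSE) {
  if (!length(set_a) || !length(set_b)) abort("both cluster sets must be non-empty")
  if (!category %in% cog_levels())
    abort("unknown category '%s'", category)
  a <- cog_indicators(clusters, set_a, category)
  b <- cog_indicators(clusters, set_b, category)
  if (sum(a) == 0 && sum(b) == 0) return(NA_real_)
  tryCatch(stats::t.test(a, b, var.equal = var_equal)$p.value,
           error = function(e) NA_real_)
}

#' Compare all COG categories between two cluster sets
#'
#' @inheritParams compare_cog_category
#' @param alpha False discovery rate for the Benjamini-Hochberg call.
#' @return Data.frame with one row per category: `category`, `p_value`
#'   (`NA` = ND) and `bh_significant` (logical, `NA` propagated), the
#'   layout of one comparison column of the reference two-group COG comparison tables.
#' @export
compare_cog_sets <- function(clusters, set_a, set_b, var_equal = FALSE,
                             alpha = 0.05) {
  p <- vapply(cog_levels(), function(cat)
    compare_cog_category(clusters, set_a, set_b, cat, var_equal = var_equal),
    numeric(1))
  data.frame(category = cog_levels(),
             p_value = unname(p),
             bh_significant = unname(bh_correct(p, alpha = alpha)),
             stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg significance calls
#'
#' Standard step-up procedure at false discovery rate `alpha`: ND entries
#' (`NA`) are excluded from the family, the m defined p-values are ranked
#' ascending, the largest k with p(k) <= k * alpha / m is found, and ranks
#' <= k are called significant. `NA` propagates to `NA`.
#'
#' @param p_values Numeric vector (possibly named), `NA` = ND.
#' @param alpha FDR level (default 0.05).
#' @return Logical vector aligned with `p_values`.
#' @export
bh_correct <- function(p_values, alpha = 0.05) {
  out <- rep(NA, length(p_values))
  names(out) <- names(p_values)
  def <- !is.na(p_values)
  if (any(def))
    out[def] <- stats::p.adjust(p_values[def], method = "BH") <= alpha
  out
}

#' Phenotype prevalence summary
#'
#' Percent of strains positive for each boolean phenotype and percent in
#' each oxygen-tolerance class, computed among strains with a recorded
#' value; denominators are reported alongside so missing data stay
#' visible.
#'
#' @param strains Strain table.
#' @return Data.frame with columns `feature`, `percent`
#'   (`NA` when the denominator is 0), `n_positive`, `denominator`.
#' @export
phenotype_summary <- function(strains) {
  pct_row <- function(feature, positive, known) {
    data.frame(feature = feature,
               percent = if (known > 0) 100 * positive / known else NA_real_,
               n_positive = positive, denominator = known,
               stringsAsFactors = FALSE)
  }
  rows <- list()
  for (col in c("growth_15C", "growth_45C")) {
    v <- strains[[col]]
    rows[[col]] <- pct_row(col, sum(v, na.rm = TRUE), sum(!is.na(v)))
  }
  ox <- strains$oxygen_class
  known <- sum(!is.na(ox))
  for (cls in oxygen_classes())
    rows[[cls]] <- pct_row(cls, sum(ox == cls, na.rm = TRUE), known)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Pearson correlation with pairwise-complete deletion
#'
#' @param x,y Numeric vectors of equal length; pairs with any missing
#'   value are dropped, and at least 3 complete pairs are required.
#' @return Pearson product-moment correlation coefficient.
#' @export
correlate <- function(x, y) {
  if (length(x) != length(y)) abort("x and y must have equal length")
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 3L) abort("need >= 3 complete pairs (have %d)", sum(ok))
  if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0)
    abort("zero variance in x or y")
  stats::cor(x[ok], y[ok])
}
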