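#' Mean and standard deviation of sugar utilization across strains
#'
#' The classification of ortholog clusters into generalist and specialist
#' groups is anchored on the distribution of the sugar utilization value
#' (number of metabolizable sugar types, glucose excluded) over all
#' strains. Strains without a recorded value are excluded and counted.
#' The sample standard deviation (denominator n-1) is used.
#'
#' @param strains Strain table from [read_strain_table()].
#' @return Object of class `gec_su_stats`: list with `mean`, `sd`,
#'   `n_strains_used`, `n_missing`.
#' @export
strain_su_stats <- function(strains) {
  su <- strains$sugar_utilization
  used <- su[!is.na(su)]
  if (length(used) < 2L)
    abort("need >= 2 strains with a sugar-utilization value (have %d)",
          length(used))
  structure(list(mean = mean(used), sd = stats::sd(used),
                 n_strains_used = length(used),
                 n_missing = sum(is.na(su))),
            class = "gec_su_stats")
}

#' @export
print.gec_su_stats <- function(x, ...) {
  cat(sprintf("sugar utilization: mean %.3f, sd %.3f (n = %d, %d missing)\n",
              x$mean, x$sd, x$n_strains_used, x$n_missing))
  invisible(x)
}

#' Average sugar utilization (ASU) per ortholog cluster
#'
#' For each cluster, ASU is the arithmetic mean of the sugar-utilization
#' values of the distinct strains in its support — each strain counts once
#' no matter how many member genes it contributes. Support strains without
#' a value are excluded from the mean (optionally replaced by the global
#' strain mean with `impute = "global_mean"`); a cluster whose support has
#' no valued strain is marked `unclassifiable`.
#'
#' @param clusters A [gec_clusters] object (singletons already dropped).
#' @param strains Strain table.
#' @param impute `"exclude"` (default) or `"global_mean"`.
#' @return A data.frame of class `gec_asu` with columns `cluster_id`,
#'   `asu`, `n_strains`, `n_strains_with_su`, `group` (all
#'   `"unclassified"` until [classify_clusters()] is applied, except
#'   `"unclassifiable"` rows).
#' @export
compute_asu <- function(clusters, strains, impute = c("exclude", "global_mean")) {
  impute <- match.arg(impute)
  stopifnot(inherits(clusters, "gec_clusters"))
  su <- strains$sugar_utilization
  names(su) <- strains$strain_id
  global_mean <- mean(su, na.rm = TRUE)
  supp <- cluster_support(clusters)
  n_strains <- vapply(supp, length, integer(1))
  asu <- n_with <- numeric(length(supp))
  for (i in seq_along(supp)) {
    vals <- su[supp[[i]]]
    if (impute == "global_mean") vals[is.na(vals)] <- global_mean
    n_with[i] <- sum(!is.na(vals))
    asu[i] <- if (n_with[i] > 0) mean(vals, na.rm = TRUE) else NA_real_
  }
  out <- data.frame(cluster_id = clusters$cluster_id,
                    asu = asu,
                    n_strains = n_strains,
                    n_strains_with_su = as.integer(n_with),
                    group = ifelse(n_with == 0, "unclassifiable", "unclassified"),
                    stringsAsFactors = FALSE)
  class(out) <- c("gec_asu", "data.frame")
  attr(out, "impute") <- impute
  out
}

#' Classify clusters as generalist / specialist / intermediate
#'
#' Applies the mean +/- 1 SD rule: a cluster is a generalist-group
#' ortholog when its ASU is strictly greater than `mean + sd` of the
#' strain-level sugar-utilization distribution, a specialist-group
#' ortholog when strictly less than `mean - sd`, and intermediate
#' otherwise. Ties at exactly the thresholds are intermediate;
#' unclassifiable clusters (no valued support strain) are preserved.
#'
#' @param asu_table A `gec_asu` data.frame from [compute_asu()].
#' @param su_stats A `gec_su_stats` object from [strain_su_stats()].
#' @return The table with `group` filled; thresholds stored in attributes
#'   `upper` and `lower`.
#' @export
classify_clusters <- function(asu_table, su_stats) {
  stopifnot(inherits(asu_table, "gec_asu"), inherits(su_stats, "gec_su_stats"))
  if (su_stats$sd == 0)
    abort("sugar-utilization sd is 0: classification thresholds collapse")
  upper <- su_stats$mean + su_stats$sd
  lower <- su_stats$mean - su_stats$sd
  grp <- asu_table$group
  open <- grp != "unclassifiable"
  grp[open] <- "intermediate"
  grp[open & asu_table$asu > upper] <- "generalist"
  grp[open & asu_table$asu < lower] <- "specialist"
  asu_table$group <- grp
  attr(asu_table, "upper") <- upper
  attr(asu_table, "lower") <- lower
  asu_table
}

#' @export
print.gec_asu <- function(x, ...) {
  cat(sprintf("gec_asu: %d clusters\n", nrow(x)))
  print(table(x$group))
  if (!is.null(attr(x, "upper")))
    cat(sprintf("  thresholds: generalist > %.4f, specialist < %.4f\n",
                attr(x, "upper"), attr(x, "lower")))
  invisible(x)
}

#' ASU-versus-support scatter table and group support summary
#'
#' Emits the plotting table (one row per cluster: ASU value and number of
#' strains) behind the ASU scatter, histogram counts on both axes, and
#' the mean support of generalist versus specialist clusters — the
#' quantity behind the observation that generalist-group orthologs tend
#' to be shared by more strains.
#'
#' @param asu_table A classified `gec_asu` table.
#' @param asu_breaks,support_breaks Histogram bin specifications passed to
#'   [hist()] (`plot = FALSE`).
#' @return List with `points` (cluster_id, asu, n_strains, group),
#'   `asu_hist` and `support_hist` (data.frames of bin mids and counts),
#'   and `group_mean_support` (named numeric; `NA` for an absent group).
#' @export
asu_scatter_summary <- function(asu_table, asu_breaks = "Sturges",
                                support_breaks = "Sturges") {
  stopifnot(inherits(asu_table, "gec_asu"))
  pts <- asu_table[c("cluster_id", "asu", "n_strains", "group")]
  ok <- !is.na(pts$asu)
  hist_df <- function(v, breaks) {
    if (!length(v)) return(data.frame(mid = numeric(0), count = integer(0)))
    h <- graphics::hist(v, breaks = breaks, plot = FALSE)
    data.frame(mid = h$mids, count = h$counts)
  }
  mean_support <- function(g) {
    s <- pts$n_strains[pts$group == g]
    if (length(s)) mean(s) else NA_real_
  }
  list(points = pts,
       asu_hist = hist_df(pts$asu[ok], asu_breaks),
       support_hist = hist_df(pts$n_strains, support_breaks),
       group_mean_support = c(generalist = mean_support("generalist"),
                              specialist = mean_support("specialist"),
                              intermediate = mean_support("intermediate")))
}
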