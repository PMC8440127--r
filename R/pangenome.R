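#' Discard strain-specific clusters
#'
#' Removes clusters whose member genes all come from a single strain
#' (strain-specific singletons), regardless of how many genes that strain
#' contributes. The number of dropped clusters is reported via `message()`.
#'
#' @param clusters A [gec_clusters] object.
#' @return The surviving clusters (support >= 2 strains).
#' @export
drop_singletons <- function(clusters) {
  stopifnot(inherits(clusters, "gec_clusters"))
  if (length(clusters) == 0L) return(clusters)
  keep <- support_sizes(clusters) >= 2L
  message(sprintf("drop_singletons: removed %d strain-specific cluster(s), kept %d",
                  sum(!keep), sum(keep)))
  clusters[which(keep)]
}

#' Partition clusters into core and accessory genomes (n-core)
#'
#' A cluster belongs to the n-core when it is conserved in at least n% of
#' the genomes: `support / n_strains >= n_percent / 100`, compared on the
#' exact fraction with no rounding of the threshold (so at 178 genomes the
#' 97-core requires support >= 172.66, i.e. >= 173 strains). The scan
#' profile records, for every n from 100 down to 91, the core size and —
#' when COG annotations are supplied — the COG-category ratio vector of
#' that core, which supports threshold selection by [select_ncore()].
#'
#' @param presence Logical presence/absence matrix from
#'   [presence_matrix()], with singletons already dropped.
#' @param n_percent Integer threshold in \[91, 100\] (default 97).
#' @param clusters Optional [gec_clusters] object carrying COG
#'   annotations, used only to fill COG ratios into the scan profile.
#' @return An object of class `gec_core_partition`: a list with
#'   `n_percent`, `core` and `accessory` cluster-id vectors, `n_strains`,
#'   and the `scan_profile` data.frame.
#' @export
compute_ncore <- function(presence, n_percent = 97, clusters = NULL) {
  if (!is.matrix(presence) || nrow(presence) == 0L || ncol(presence) == 0L)
    abort("presence matrix is empty")
  if (!(n_percent %% 1 == 0) || n_percent < 91 || n_percent > 100)
    abort("n_percent must be an integer in [91, 100]")
  n_strains <- nrow(presence)
  support <- colSums(presence)

  core_at <- function(n) colnames(presence)[support / n_strains >= n / 100]

  scan_ns <- 100:91
  profile <- data.frame(n_percent = scan_ns,
                        core_size = vapply(scan_ns, function(n)
                          length(core_at(n)), integer(1)))
  if (!is.null(clusters)) {
    ratios <- t(vapply(scan_ns, function(n) {
      ids <- core_at(n)
      if (!length(ids)) rep(NA_real_, length(cog_levels()))
      else as.numeric(cog_ratios(clusters, ids))
    }, numeric(length(cog_levels()))))
    colnames(ratios) <- cog_levels()
    profile <- cbind(profile, as.data.frame(ratios))
  }

  core <- core_at(n_percent)
  structure(list(n_percent = n_percent,
                 core = core,
                 accessory = setdiff(colnames(presence), core),
                 n_strains = n_strains,
                 scan_profile = profile),
            class = "gec_core_partition")
}

#' @export
print.gec_core_partition <- function(x, ...) {
  cat(sprintf("gec_core_partition: %d-core over %d strains\n",
              x$n_percent, x$n_strains))
  cat(sprintf("  core: %d clusters; accessory: %d clusters\n",
              length(x$core), length(x$accessory)))
  invisible(x)
}

#' Choose the n-core threshold from the scan profile
#'
#' Strategy `"fixed"` simply returns `fixed_n` (default 97, the threshold
#' adopted for this family's pan-genome). Strategy `"stability"` looks for
#' the largest n whose core COG-ratio vector differs from that of n-1 by
#' an L1 distance below `tolerance`, i.e. the most stringent threshold at
#' which the functional profile of the core has stabilised; when no n
#' qualifies it falls back to `fixed_n` with a warning.
#'
#' @param partition A `gec_core_partition` (or its `scan_profile`).
#' @param strategy `"fixed"` or `"stability"`.
#' @param fixed_n Integer returned by the fixed strategy (default 97).
#' @param tolerance L1 threshold for the stability strategy.
#' @return The selected integer n, with the rationale in attribute
#'   `"rationale"`.
#' @export
select_ncore <- function(partition, strategy = c("fixed", "stability"),
                         fixed_n = 97, tolerance = 0.02) {
  strategy <- match.arg(strategy)
  profile <- if (inherits(partition, "gec_core_partition"))
    partition$scan_profile else partition
  if (strategy == "fixed") {
    return(structure(fixed_n,
                     rationale = sprintf("fixed strategy: n = %d", fixed_n)))
  }
  cols <- intersect(cog_levels(), names(profile))
  if (!length(cols))
    abort("stability strategy needs COG ratio columns in the scan profile")
  m <- as.matrix(profile[cols])
  ns <- profile$n_percent
  for (n in sort(ns, decreasing = TRUE)) {
    i <- match(n, ns); j <- match(n - 1, ns)
    if (is.na(j)) next
    d <- sum(abs(m[i, ] - m[j, ]))
    if (is.finite(d) && d < tolerance)
      return(structure(n, rationale = sprintf(
        "stability strategy: L1 distance %.4g between %d- and %d-core below %.4g",
        d, n, n - 1, tolerance)))
  }
  warn("no n meets the stability tolerance %.4g; falling back to fixed n = %d",
       tolerance, fixed_n)
  structure(fixed_n,
            rationale = sprintf("fallback to fixed n = %d", fixed_n))
}
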