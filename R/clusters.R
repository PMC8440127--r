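#' Ortholog cluster collection
#'
#' A `gec_clusters` object holds ortholog clusters across genomes: for each
#' cluster its identifier, the member genes as (strain, gene) pairs, and an
#' optional set of single-letter COG functional categories. It is the unit
#' of sharing used throughout the pipeline; a cluster whose genes all come
#' from one strain is "strain-specific" (a singleton in pan-genome terms).
#'
#' @param cluster_id Character vector of unique cluster identifiers.
#' @param members List, one element per cluster, each a data.frame with
#'   columns `strain_id` and `gene_id` (at least one row per cluster).
#' @param cog List of character vectors (possibly empty) of COG letters,
#'   one per cluster, or `NULL` for none assigned yet.
#' @return An object of class `gec_clusters`.
#' @export
gec_clusters <- function(cluster_id, members, cog = NULL) {
  cluster_id <- as.character(cluster_id)
  if (anyDuplicated(cluster_id))
    abort("duplicate cluster_id: %s",
          paste(unique(cluster_id[duplicated(cluster_id)]), collapse = ", "))
  if (length(members) != length(cluster_id))
    abort("members must have one entry per cluster")
  empty <- vapply(members, function(m) is.null(m) || nrow(m) == 0L, logical(1))
  if (any(empty))
    abort("empty cluster (no member genes): %s",
          paste(cluster_id[empty], collapse = ", "))
  members <- lapply(members, function(m) {
    m <- data.frame(strain_id = as.character(m$strain_id),
                    gene_id = as.character(m$gene_id),
                    stringsAsFactors = FALSE)
    rownames(m) <- NULL
    m
  })
  if (is.null(cog)) cog <- rep(list(character(0)), length(cluster_id))
  bad <- unlist(lapply(cog, function(x) setdiff(x, cog_alphabet())))
  if (length(bad))
    abort("illegal COG letter(s): %s", paste(unique(bad), collapse = ", "))
  structure(list(cluster_id = cluster_id, members = members, cog = cog),
            class = "gec_clusters")
}

#' @export
length.gec_clusters <- function(x) length(x$cluster_id)

#' Subset clusters by index or cluster id
#' @param x A `gec_clusters` object.
#' @param i Integer, logical, or character (cluster id) index.
#' @param ... Ignored.
#' @return A `gec_clusters` object with the selected clusters.
#' @export
`[.gec_clusters` <- function(x, i, ...) {
  if (is.character(i)) {
    j <- match(i, x$cluster_id)
    if (anyNA(j)) abort("unknown cluster id(s): %s",
                        paste(i[is.na(j)], collapse = ", "))
    i <- j
  }
  gec_clusters(x$cluster_id[i], x$members[i], x$cog[i])
}

#' @export
print.gec_clusters <- function(x, ...) {
  supp <- support_sizes(x)
  cat(sprintf("gec_clusters: %d clusters over %d strains\n",
              length(x), length(cluster_strains(x))))
  cat(sprintf("  support sizes: min %d, median %s, max %d\n",
              min(supp), format(stats::median(supp)), max(supp)))
  n_cog <- sum(vapply(x$cog, length, integer(1)) > 0L)
  cat(sprintf("  COG-annotated clusters: %d\n", n_cog))
  invisible(x)
}

#' Strains supporting each cluster
#'
#' @param clusters A `gec_clusters` object.
#' @return A list of character vectors: the distinct strains carrying at
#'   least one member gene of each cluster (the cluster's support).
#' @export
cluster_support <- function(clusters) {
  stopifnot(inherits(clusters, "gec_clusters"))
  lapply(clusters$members, function(m) sort(unique(m$strain_id)))
}

#' Support size (number of distinct strains) per cluster
#' @param clusters A `gec_clusters` object.
#' @return Named integer vector.
#' @export
support_sizes <- function(clusters) {
  n <- vapply(cluster_support(clusters), length, integer(1))
  names(n) <- clusters$cluster_id
  n
}

# all strains appearing in any cluster, sorted
cluster_strains <- function(clusters) {
  sort(unique(unlist(lapply(clusters$members, `[[`, "strain_id"))))
}

#' Presence/absence matrix of clusters across strains
#'
#' Converts cluster membership to a logical matrix with one row per strain
#' and one column per cluster; a cell is `TRUE` when the strain carries at
#' least one member gene of the cluster (in-paralogs collapse to presence).
#'
#' @param clusters A `gec_clusters` object.
#' @param strains Optional character vector of strain ids (e.g. from the
#'   strain table) fixing the row set; defaults to the strains observed in
#'   the clusters. Strains never observed get all-`FALSE` rows.
#' @return Logical matrix with dimnames (sorted strain ids, cluster ids in
#'   input order).
#' @export
presence_matrix <- function(clusters, strains = NULL) {
  stopifnot(inherits(clusters, "gec_clusters"))
  observed <- cluster_strains(clusters)
  if (is.null(strains)) {
    strains <- observed
  } else {
    strains <- sort(unique(as.character(strains)))
    missing <- setdiff(observed, strains)
    if (length(missing))
      warn("clusters reference %d strain(s) absent from the strain list: %s",
           length(missing), paste(utils::head(missing, 5), collapse = ", "))
  }
  pm <- matrix(FALSE, nrow = length(strains), ncol = length(clusters),
               dimnames = list(strains, clusters$cluster_id))
  supp <- cluster_support(clusters)
  for (j in seq_along(supp)) {
    s <- intersect(supp[[j]], strains)
    pm[s, j] <- TRUE
  }
  pm
}
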