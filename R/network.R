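#' Build a shared-ortholog network over genomes
#'
#' Every strain is a node; for each unordered pair of strains the shared
#' count is the number of selected-group clusters (e.g. the generalist-
#' classified orthologs) whose support contains both strains, and an edge
#' is created when the shared count is strictly greater than the
#' threshold ("more than five" with the default 5). Isolated nodes are
#' retained, so the node count always equals the strain count.
#'
#' @param clusters A [gec_clusters] object.
#' @param cluster_ids Ids of the selected group clusters (e.g. generalist
#'   clusters from [classify_clusters()]); an empty set yields an
#'   edgeless graph.
#' @param strains Strain table (supplies the node set and the `genus` and
#'   `sugar_utilization` node attributes).
#' @param threshold Minimum shared count that must be exceeded
#'   (default 5).
#' @param group Label stored as a graph attribute (e.g. `"generalist"`).
#' @return An undirected igraph object with node attributes `genus` and
#'   `sugar_utilization`, edge attribute `shared_count`, and graph
#'   attributes `group` and `threshold`.
#' @export
build_gec_network <- function(clusters, cluster_ids, strains,
                              threshold = 5, group = NA_character_) {
  if (is.null(strains) || nrow(strains) == 0L) abort("empty strain list")
  if (threshold < 0) abort("threshold must be >= 0")
  ids <- sort(strains$strain_id)
  shared <- shared_counts(clusters, cluster_ids, ids)
  ut <- upper.tri(shared)
  sel <- which(ut & shared > threshold, arr.ind = TRUE)
  edges <- data.frame(from = ids[sel[, 1]], to = ids[sel[, 2]],
                      shared_count = shared[sel],
                      stringsAsFactors = FALSE)
  vertices <- data.frame(
    name = ids,
    genus = strains$genus[match(ids, strains$strain_id)],
    sugar_utilization = strains$sugar_utilization[match(ids, strains$strain_id)],
    stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = vertices)
  igraph::graph_attr(g, "group") <- group
  igraph::graph_attr(g, "threshold") <- threshold
  g
}

#' Pairwise shared-cluster counts between strains
#'
#' @param clusters A [gec_clusters] object.
#' @param cluster_ids Cluster ids defining the group.
#' @param strains Character vector of strain ids (rows/cols of the
#'   result).
#' @return Symmetric integer matrix of co-presence counts (diagonal =
#'   number of group clusters carrying the strain).
#' @export
shared_counts <- function(clusters, cluster_ids, strains) {
  strains <- as.character(strains)
  m <- matrix(0L, length(strains), length(strains),
              dimnames = list(strains, strains))
  if (length(cluster_ids)) {
    pm <- presence_matrix(clusters[cluster_ids], strains = strains)
    pm <- pm[strains, , drop = FALSE] # caller's order, not sorted
    m <- tcrossprod(pm * 1L)
    storage.mode(m) <- "integer"
  }
  m
}

#' Extract communities from a shared-ortholog network
#'
#' The default extracts the connected components of the thresholded graph
#' and discards singletons (minimum community size 2). Greedy modularity
#' optimisation is available for denser graphs.
#'
#' @param graph igraph object from [build_gec_network()].
#' @param method `"components"` (default) or `"greedy_modularity"`.
#' @return Object of class `gec_communities`: list with `communities`
#'   (list of sorted strain-id vectors, ordered by decreasing size then
#'   lexicographically), `method`, `n`, `size_max`, `size_min` (the last
#'   two `NA` when there are no communities).
#' @export
extract_communities <- function(graph,
                                method = c("components", "greedy_modularity")) {
  method <- match.arg(method)
  memb <- if (method == "components") {
    igraph::components(graph)$membership
  } else {
    igraph::membership(igraph::cluster_fast_greedy(graph))
  }
  parts <- split(names(memb), memb)
  parts <- lapply(parts, sort)
  parts <- parts[vapply(parts, length, integer(1)) >= 2L]
  ord <- order(-vapply(parts, length, integer(1)),
               vapply(parts, `[`, "", 1L))
  parts <- unname(parts[ord])
  sizes <- vapply(parts, length, integer(1))
  structure(list(communities = parts, method = method,
                 n = length(parts),
                 size_max = if (length(sizes)) max(sizes) else NA_integer_,
                 size_min = if (length(sizes)) min(sizes) else NA_integer_),
            class = "gec_communities")
}

#' @export
print.gec_communities <- function(x, ...) {
  cat(sprintf("gec_communities (%s): %d communities", x$method, x$n))
  if (x$n > 0) cat(sprintf(", sizes %d..%d", x$size_min, x$size_max))
  cat("\n")
  invisible(x)
}

#' Within- versus cross-genus edge mixing
#'
#' Quantifies how far a shared-ortholog network reaches across genera:
#' counts and fractions of within-genus versus cross-genus edges,
#' per-genus degree summaries, and the genera incident to no edge at all.
#'
#' @param graph igraph object with a `genus` node attribute.
#' @return List with `n_edges`, `n_within`, `n_cross`, `fraction_cross`
#'   (`NA` for an edgeless graph), `genus_degree` (data.frame), and
#'   `genera_without_edges` (character).
#' @export
genus_mixing <- function(graph) {
  genus <- igraph::V(graph)$genus
  names(genus) <- igraph::V(graph)$name
  e <- igraph::as_data_frame(graph, what = "edges")
  n_edges <- nrow(e)
  cross <- if (n_edges) genus[e$from] != genus[e$to] else logical(0)
  deg <- igraph::degree(graph)
  gd <- stats::aggregate(list(total_degree = deg,
                              n_connected = as.integer(deg > 0)),
                         by = list(genus = genus), FUN = sum)
  gd <- gd[order(gd$genus), , drop = FALSE]
  rownames(gd) <- NULL
  list(n_edges = n_edges,
       n_within = sum(!cross),
       n_cross = sum(cross),
       fraction_cross = if (n_edges) sum(cross) / n_edges else NA_real_,
       genus_degree = gd,
       genera_without_edges = sort(setdiff(unique(genus),
                                           unique(genus[deg > 0]))))
}

#' Community summary table
#'
#' @param graph igraph object (supplies genus labels).
#' @param communities A `gec_communities` object.
#' @return List with `n_communities`, `size_max`, `size_min`, and a
#'   data.frame `members` (community_id, strain_id, genus) listing every
#'   community member.
#' @export
network_summary <- function(graph, communities) {
  stopifnot(inherits(communities, "gec_communities"))
  genus <- stats::setNames(igraph::V(graph)$genus, igraph::V(graph)$name)
  members <- if (communities$n == 0) {
    data.frame(community_id = integer(0), strain_id = character(0),
               genus = character(0), stringsAsFactors = FALSE)
  } else {
    do.call(rbind, lapply(seq_along(communities$communities), function(i) {
      s <- communities$communities[[i]]
      data.frame(community_id = i, strain_id = s,
                 genus = unname(genus[s]), stringsAsFactors = FALSE)
    }))
  }
  list(n_communities = communities$n,
       size_max = communities$size_max,
       size_min = communities$size_min,
       members = members)
}

#' Adjusted Rand index between extracted and reference communities
#'
#' Compares two community structures over a common strain universe. Every
#' strain outside any community gets its own singleton label, so strains
#' correctly left unassigned count as agreement.
#'
#' @param communities A `gec_communities` object or list of strain-id
#'   sets.
#' @param reference List of strain-id sets (e.g. planted ground truth).
#' @param strains Character vector: the strain universe (defaults to the
#'   union of both structures).
#' @return Adjusted Rand index.
#' @export
community_ari <- function(communities, reference, strains = NULL) {
  comm <- if (inherits(communities, "gec_communities"))
    communities$communities else communities
  lab <- function(parts, universe) {
    l <- stats::setNames(paste0("s_", seq_along(universe)), universe)
    for (i in seq_along(parts)) {
      hit <- intersect(parts[[i]], universe)
      l[hit] <- paste0("c_", i)
    }
    l
  }
  if (is.null(strains))
    strains <- sort(unique(c(unlist(comm), unlist(reference))))
  mclust::adjustedRandIndex(lab(comm, strains), lab(reference, strains))
}
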