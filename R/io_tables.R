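#' Read a strain phenotype/genome-feature table
#'
#' Parses the tab-separated strain metadata table (one row per genome) that
#' drives the whole analysis: taxonomy, the six phenotypic features (sugar
#' utilization value, growth at 15\eqn{^\circ}C and 45\eqn{^\circ}C, and the
#' three mutually exclusive oxygen-tolerance classes) and the genomic
#' features (genome size, CDS count, HGT-derived CDS count, GC content,
#' rRNA/tRNA/CRISPR counts), plus an optional free-text isolation source.
#'
#' Missing cells stay missing: no imputation happens at load time, because
#' each downstream stage owns its own rule (the regression stage
#' mean-imputes; the ASU stage excludes).
#'
#' @param path Path to a TSV file with a header row.
#' @param gc_unit How the `gc_content` column is expressed: `"auto"`
#'   (default; values > 1 are taken as percent and divided by 100),
#'   `"fraction"`, or `"percent"`.
#' @param true_values,false_values Tokens accepted as boolean yes/no
#'   (case-insensitive).
#' @param na_strings Tokens treated as missing.
#' @return A data.frame with one row per strain, typed columns, and
#'   `gc_content` stored as a fraction in (0, 1).
#' @export
read_strain_table <- function(path,
                              gc_unit = c("auto", "fraction", "percent"),
                              true_values = c("yes", "y", "true", "t", "1", "+"),
                              false_values = c("no", "n", "false", "f", "0", "-"),
                              na_strings = c("", "NA", "na", "ND")) {
  gc_unit <- match.arg(gc_unit)
  raw <- read_tsv(path)
  required <- c("strain_id", "genus", "species", "sugar_utilization",
                "growth_15C", "growth_45C", "oxygen_class", "genome_size",
                "n_cds", "n_hgt_cds", "gc_content", "n_rrna", "n_trna",
                "n_crispr")
  miss <- setdiff(required, names(raw))
  if (length(miss))
    abort("strain table %s lacks required column(s): %s",
          path, paste(miss, collapse = ", "))

  parse_num <- function(col, integer = FALSE) {
    v <- trimws(raw[[col]])
    v[v %in% na_strings] <- NA
    out <- suppressWarnings(as.numeric(v))
    bad <- which(!is.na(v) & is.na(out))
    if (length(bad))
      abort("unparseable numeric value '%s' in column '%s', row %d",
            v[bad[1]], col, bad[1])
    if (integer) out <- as.integer(round(out))
    out
  }
  parse_bool <- function(col) {
    v <- tolower(trimws(raw[[col]]))
    v[v %in% tolower(na_strings)] <- NA
    out <- rep(NA, length(v))
    out[v %in% tolower(true_values)] <- TRUE
    out[v %in% tolower(false_values)] <- FALSE
    bad <- which(!is.na(v) & is.na(out))
    if (length(bad))
      abort("unparseable boolean value '%s' in column '%s', row %d",
            raw[[col]][bad[1]], col, bad[1])
    out
  }

  strain_id <- trimws(raw$strain_id)
  dup <- unique(strain_id[duplicated(strain_id)])
  if (length(dup))
    abort("duplicate strain_id: %s", paste(dup, collapse = ", "))

  oxy <- trimws(raw$oxygen_class)
  oxy[oxy %in% na_strings] <- NA
  bad_ox <- setdiff(stats::na.omit(unique(oxy)), oxygen_classes())
  if (length(bad_ox))
    abort("unknown oxygen_class label(s): %s (allowed: %s)",
          paste(bad_ox, collapse = ", "),
          paste(oxygen_classes(), collapse = ", "))

  gc <- parse_num("gc_content")
  if (gc_unit == "percent" || (gc_unit == "auto" && any(gc > 1, na.rm = TRUE)))
    gc <- gc / 100

  out <- data.frame(
    strain_id = strain_id,
    genus = trimws(raw$genus),
    species = trimws(raw$species),
    sugar_utilization = parse_num("sugar_utilization"),
    growth_15C = parse_bool("growth_15C"),
    growth_45C = parse_bool("growth_45C"),
    oxygen_class = oxy,
    genome_size = parse_num("genome_size"),
    n_cds = parse_num("n_cds", integer = TRUE),
    n_hgt_cds = parse_num("n_hgt_cds", integer = TRUE),
    gc_content = gc,
    n_rrna = parse_num("n_rrna", integer = TRUE),
    n_trna = parse_num("n_trna", integer = TRUE),
    n_crispr = parse_num("n_crispr", integer = TRUE),
    stringsAsFactors = FALSE
  )
  out$isolation_source <- if ("isolation_source" %in% names(raw))
    trimws(raw$isolation_source) else NA_character_

  if (any(out$sugar_utilization < 0, na.rm = TRUE))
    abort("negative sugar_utilization values present")
  over <- which(out$n_hgt_cds > out$n_cds)
  if (length(over))
    abort("n_hgt_cds exceeds n_cds for strain(s): %s",
          paste(out$strain_id[over], collapse = ", "))
  bad_gc <- which(!is.na(out$gc_content) &
                    (out$gc_content <= 0 | out$gc_content >= 1))
  if (length(bad_gc))
    abort("gc_content outside (0,1) after normalization for strain(s): %s",
          paste(out$strain_id[bad_gc], collapse = ", "))
  out
}

#' Write a strain table as TSV
#'
#' Inverse of [read_strain_table()]: booleans become yes/no, GC content is
#' written as a fraction, missing values as empty cells.
#'
#' @param strains Strain data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_strain_table <- function(strains, path) {
  out <- strains
  for (col in c("growth_15C", "growth_45C"))
    out[[col]] <- ifelse(is.na(out[[col]]), "",
                         ifelse(out[[col]], "yes", "no"))
  write_tsv(out, path)
}

#' Read ortholog groups
#'
#' Reads ortholog-cluster membership in either the wide layout produced by
#' ortholog-inference tools such as SonicParanoid (first column the cluster
#' id, then one column per genome holding comma-separated gene ids with
#' `"*"` marking absence) or a generic long layout with columns
#' `cluster_id` and `strain_id:gene_id`.
#'
#' @param path Path to the TSV file.
#' @param format `"sonicparanoid"` (wide, default) or `"long"`.
#' @param strains Optional strain table (or character vector of strain
#'   ids); genome columns absent from it trigger a warning and are listed
#'   in the `unknown_strains` attribute of the result.
#' @return A [gec_clusters] object (COG categories empty; see
#'   [annotate_cogs()]).
#' @export
read_ortholog_groups <- function(path,
                                 format = c("sonicparanoid", "long"),
                                 strains = NULL) {
  format <- match.arg(format)
  known <- if (is.null(strains)) NULL
           else if (is.data.frame(strains)) strains$strain_id
           else as.character(strains)

  if (format == "sonicparanoid") {
    raw <- read_tsv(path)
    if (ncol(raw) < 2L)
      abort("ortholog group table needs a cluster-id column plus >=1 genome column")
    genomes <- names(raw)[-1]
    ids <- trimws(raw[[1]])
    members <- vector("list", nrow(raw))
    for (i in seq_len(nrow(raw))) {
      sid <- character(0); gid <- character(0)
      for (g in genomes) {
        cell <- trimws(raw[[g]][i])
        if (cell == "*" || cell == "") next
        genes <- trimws(strsplit(cell, ",", fixed = TRUE)[[1]])
        genes <- genes[nzchar(genes)]
        sid <- c(sid, rep(g, length(genes)))
        gid <- c(gid, genes)
      }
      if (!length(gid))
        abort("cluster '%s' has no member genes (all cells absent)", ids[i])
      members[[i]] <- data.frame(strain_id = sid, gene_id = gid,
                                 stringsAsFactors = FALSE)
    }
  } else {
    raw <- read_tsv(path)
    need <- c("cluster_id", "member")
    if (!all(need %in% names(raw)))
      abort("long-format ortholog table needs columns: %s",
            paste(need, collapse = ", "))
    pieces <- strsplit(raw$member, ":", fixed = TRUE)
    bad <- which(vapply(pieces, length, integer(1)) != 2L)
    if (length(bad))
      abort("long-format member '%s' (row %d) is not strain_id:gene_id",
            raw$member[bad[1]], bad[1])
    df <- data.frame(cluster_id = trimws(raw$cluster_id),
                     strain_id = vapply(pieces, `[`, "", 1L),
                     gene_id = vapply(pieces, `[`, "", 2L),
                     stringsAsFactors = FALSE)
    ids <- unique(df$cluster_id)
    members <- unname(lapply(split(df[c("strain_id", "gene_id")],
                                   df$cluster_id),
                             function(m) { rownames(m) <- NULL; m })[ids])
  }

  cl <- gec_clusters(ids, members)
  if (!is.null(known)) {
    unknown <- setdiff(cluster_strains(cl), known)
    if (length(unknown))
      warn("%d genome(s) in the ortholog table are absent from the strain table: %s",
           length(unknown), paste(utils::head(unknown, 5), collapse = ", "))
    attr(cl, "unknown_strains") <- unknown
  }
  cl
}

#' Write ortholog groups in the wide layout
#'
#' @param clusters A [gec_clusters] object.
#' @param path Output path.
#' @param strains Optional strain ids fixing the genome columns (defaults
#'   to the strains observed in the clusters, sorted).
#' @return `path`, invisibly.
#' @export
write_ortholog_groups <- function(clusters, path, strains = NULL) {
  stopifnot(inherits(clusters, "gec_clusters"))
  genomes <- if (is.null(strains)) cluster_strains(clusters)
             else sort(unique(as.character(strains)))
  rows <- lapply(clusters$members, function(m) {
    cells <- vapply(genomes, function(g) {
      genes <- m$gene_id[m$strain_id == g]
      if (length(genes)) paste(genes, collapse = ",") else "*"
    }, character(1))
    cells
  })
  out <- data.frame(cluster_id = clusters$cluster_id,
                    do.call(rbind, rows),
                    check.names = FALSE, stringsAsFactors = FALSE)
  names(out) <- c("cluster_id", genomes)
  write_tsv(out, path)
}

#' Attach COG functional categories to clusters
#'
#' Reads a two-column map (`cluster_id`, `cog`, where `cog` is one or more
#' single letters from the 26-letter COG alphabet, e.g. `"G"` or `"GE"`)
#' and fills the `cog` field of each mapped cluster. Unmapped clusters keep
#' an empty set and are counted as `Not_assigned` downstream.
#'
#' @param clusters A [gec_clusters] object.
#' @param cog_map Path to the map TSV, or a data.frame with columns
#'   `cluster_id` and `cog`.
#' @return The clusters with `cog` filled.
#' @export
annotate_cogs <- function(clusters, cog_map) {
  stopifnot(inherits(clusters, "gec_clusters"))
  map <- if (is.data.frame(cog_map)) cog_map else read_tsv(cog_map)
  if (!all(c("cluster_id", "cog") %in% names(map)))
    abort("COG map needs columns cluster_id and cog")
  unknown <- setdiff(map$cluster_id, clusters$cluster_id)
  if (length(unknown))
    warn("COG map has %d entr%s for unknown clusters (e.g. %s)",
         length(unknown), if (length(unknown) == 1) "y" else "ies",
         paste(utils::head(unknown, 3), collapse = ", "))
  letters_of <- function(s) {
    s <- gsub("[ ,]", "", s)
    if (!nzchar(s)) return(character(0))
    l <- strsplit(s, "")[[1]]
    bad <- setdiff(l, cog_alphabet())
    if (length(bad))
      abort("illegal COG letter(s) in map: %s", paste(unique(bad), collapse = ", "))
    unique(l)
  }
  assigned <- lapply(map$cog, letters_of)
  idx <- match(map$cluster_id, clusters$cluster_id)
  for (k in which(!is.na(idx))) clusters$cog[[idx[k]]] <- assigned[[k]]
  clusters
}

#' Write a cluster-to-COG map as TSV
#' @param clusters A [gec_clusters] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cog_map <- function(clusters, path) {
  has <- vapply(clusters$cog, length, integer(1)) > 0L
  write_tsv(data.frame(
    cluster_id = clusters$cluster_id[has],
    cog = vapply(clusters$cog[has], paste, "", collapse = ""),
    stringsAsFactors = FALSE), path)
}

#' Export a shared-ortholog network
#'
#' Writes a genome network built by [build_gec_network()] either as
#' GraphML (node attributes `genus`, `sugar_utilization`, `group`; edge
#' attribute `shared_count`) or as a plain edge-list TSV with columns
#' `strain_a`, `strain_b`, `shared_count`, `group`. Node order is
#' lexicographic in both formats.
#'
#' @param graph An igraph object from [build_gec_network()].
#' @param path Output path.
#' @param format `"edge_tsv"` or `"graphml"`.
#' @return `path`, invisibly.
#' @export
export_network <- function(graph, path, format = c("edge_tsv", "graphml")) {
  format <- match.arg(format)
  stopifnot(inherits(graph, "igraph"))
  ord <- order(igraph::V(graph)$name)
  graph <- igraph::permute(graph, order(ord))
  if (format == "graphml") {
    igraph::write_graph(graph, path, format = "graphml")
  } else {
    e <- igraph::as_data_frame(graph, what = "edges")
    grp <- igraph::graph_attr(graph, "group") %||% NA_character_
    out <- data.frame(strain_a = pmin(e$from, e$to),
                      strain_b = pmax(e$from, e$to),
                      shared_count = if (nrow(e)) e$shared_count else integer(0),
                      group = rep(grp, nrow(e)),
                      stringsAsFactors = FALSE)
    out <- out[order(out$strain_a, out$strain_b), , drop = FALSE]
    write_tsv(out, path)
  }
  invisible(path)
}

#' Import a network written by [export_network()]
#'
#' @param path Input path.
#' @param format `"edge_tsv"` or `"graphml"`. The edge-TSV round trip
#'   recovers only strains incident to an edge; GraphML preserves isolated
#'   nodes too.
#' @return An igraph object.
#' @export
import_network <- function(path, format = c("edge_tsv", "graphml")) {
  format <- match.arg(format)
  if (format == "graphml") return(igraph::read_graph(path, format = "graphml"))
  e <- read_tsv(path)
  g <- igraph::graph_from_data_frame(
    data.frame(from = e$strain_a, to = e$strain_b,
               shared_count = as.integer(e$shared_count)),
    directed = FALSE)
  if (nrow(e)) igraph::graph_attr(g, "group") <- e$group[1]
  g
}
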