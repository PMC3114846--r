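# Readers and writers for the pipeline's plain-text formats: network
# edge-list TSV and SIF, GMT and two-column gene-term annotation TSV,
# cluster TSV, and the HIN edge list. All writers emit a `#` comment
# header (tool version, optional seed/config hash); all readers skip `#`
# lines. read(write(x)) is the identity on canonicalized structures.

read_table_checked <- function(path, required, what) {
  if (!file.exists(path)) stop_config("%s file not found: %s", what, path)
  df <- tryCatch(read_tsv_skip_comments(path),
                 error = function(e) stop_format("cannot parse %s file %s: %s",
                                                 what, path,
                                                 conditionMessage(e)))
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop_format("%s file %s is missing column '%s'", what, path, missing[1L])
  df
}

#' Export a network as an edge-list TSV
#'
#' Columns `node_a`, `node_b`, `kind`, `weight`, `shared_count`,
#' `sources`. Bipartite edges have kind `gene-disease`, weight 1 and the
#' pipe-joined source set; projection edges have kind
#' `<side>-projection`, the overlap weight and the shared-neighbor count.
#'
#' @param net A `dgnet_bipartite` or `dgnet_projection`.
#' @param path Output path.
#' @param seed Optional seed recorded in the header.
#' @param hash Optional configuration hash recorded in the header.
#' @return The path, invisibly.
#' @export
write_edgelist <- function(net, path, seed = NULL, hash = NULL) {
  if (inherits(net, "dgnet_bipartite")) {
    df <- data.frame(
      node_a = net$edges$gene_id, node_b = net$edges$disease_id,
      kind = "gene-disease", weight = 1,
      shared_count = NA_integer_,
      sources = vapply(net$edges$sources, paste, character(1),
                       collapse = "|"),
      stringsAsFactors = FALSE)
  } else if (inherits(net, "dgnet_projection")) {
    df <- data.frame(
      node_a = net$edges$node_a, node_b = net$edges$node_b,
      kind = paste0(net$side, "-projection"),
      weight = net$edges$weight,
      shared_count = net$edges$shared_count,
      sources = vapply(net$edges$shared, paste, character(1),
                       collapse = "|"),
      stringsAsFactors = FALSE)
  } else stop_input("write_edgelist expects a bipartite or projection network")
  write_tsv_with_header(df, path, seed = seed, hash = hash)
}

#' Read an edge-list TSV written by [write_edgelist()]
#'
#' @param path Path to the file.
#' @return data.frame with the edge-list columns.
#' @export
read_edgelist <- function(path) {
  df <- read_table_checked(path, c("node_a", "node_b", "kind", "weight"),
                           "edge-list")
  df$node_a <- as.character(df$node_a)
  df$node_b <- as.character(df$node_b)
  df
}

#' Write / read a network in SIF format
#'
#' One `node_a  relation  node_b` triple per line. On reading, duplicate
#' undirected edges (`a rel b` and `b rel a`) collapse to one canonical
#' pair.
#'
#' @param net A `dgnet_bipartite`, `dgnet_projection` or `dgnet_hin`.
#' @param path File path.
#' @return `write_sif`: the path, invisibly. `read_sif`: data.frame
#'   `node_a`, `rel`, `node_b` with canonical unordered pairs.
#' @export
write_sif <- function(net, path) {
  if (inherits(net, "dgnet_bipartite")) {
    df <- data.frame(node_a = net$edges$gene_id, rel = "associates",
                     node_b = net$edges$disease_id,
                     stringsAsFactors = FALSE)
  } else if (inherits(net, "dgnet_projection")) {
    df <- data.frame(node_a = net$edges$node_a, rel = "shares",
                     node_b = net$edges$node_b, stringsAsFactors = FALSE)
  } else if (inherits(net, "dgnet_hin")) {
    df <- data.frame(node_a = net$edges$a, rel = "interacts",
                     node_b = net$edges$b, stringsAsFactors = FALSE)
  } else stop_input("write_sif expects a dgnet network object")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(output_header(), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_sif
#' @export
read_sif <- function(path) {
  if (!file.exists(path)) stop_config("SIF file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 3L)
  if (length(bad))
    stop_format("SIF line %d does not have 3 tab-separated fields", bad[1L])
  a <- vapply(parts, `[`, character(1), 1L)
  rel <- vapply(parts, `[`, character(1), 2L)
  b <- vapply(parts, `[`, character(1), 3L)
  lo <- pmin(a, b); hi <- pmax(a, b)
  keep <- !duplicated(paste(lo, rel, hi, sep = "\r"))
  out <- data.frame(node_a = lo[keep], rel = rel[keep],
                    node_b = hi[keep], stringsAsFactors = FALSE)
  out <- out[order(out$node_a, out$node_b), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read / write gene-set annotations
#'
#' `read_gmt()` parses the GMT gene-set format (one term per line:
#' `term_id<TAB>description<TAB>gene...`); `write_gmt()` is its inverse.
#' `read_annotation_tsv()` parses a two-column `gene_id  term_id` table.
#' All return / consume a `dgnet_annotation`.
#'
#' @param path File path.
#' @param catalog_name Catalog label stored in the annotation map.
#' @return A `dgnet_annotation` (readers); the path, invisibly (writer).
#' @export
read_gmt <- function(path, catalog_name = basename(path)) {
  if (!file.exists(path)) stop_config("GMT file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !startsWith(lines, "#") & nzchar(lines)
  parts <- strsplit(lines[keep], "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3L)
  if (length(bad))
    stop_format("GMT line %d has fewer than 3 fields", which(keep)[bad[1L]])
  g2t <- list()
  for (p in parts) {
    term <- p[1L]
    for (g in unique(p[-(1:2)])) g2t[[g]] <- c(g2t[[g]], term)
  }
  annotation_map(g2t, catalog_name)
}

#' @rdname read_gmt
#' @param ann A `dgnet_annotation` to write.
#' @export
write_gmt <- function(ann, path) {
  stopifnot(inherits(ann, "dgnet_annotation"))
  terms <- sort(unique(unlist(ann$gene_to_terms, use.names = FALSE)))
  lines <- vapply(terms, function(t) {
    members <- sort(names(ann$gene_to_terms)[vapply(
      ann$gene_to_terms, function(x) t %in% x, logical(1))])
    paste(c(t, ann$catalog_name, members), collapse = "\t")
  }, character(1))
  writeLines(c(output_header(), lines), path)
  invisible(path)
}

#' @rdname read_gmt
#' @export
read_annotation_tsv <- function(path, catalog_name = basename(path)) {
  df <- read_table_checked(path, c("gene_id", "term_id"), "annotation")
  annotation_map(lapply(split(as.character(df$term_id),
                              as.character(df$gene_id)), unique),
                 catalog_name)
}

#' Read a protein-interaction network from an edge-list TSV or SIF file
#'
#' Accepts either a SIF file (3 columns, no header) or a TSV with
#' header columns `node_a`/`node_b` (or any two-column table).
#'
#' @param path File path.
#' @return A `dgnet_hin`.
#' @export
read_hin <- function(path) {
  if (!file.exists(path)) stop_config("HIN file not found: %s", path)
  first <- readLines(path, n = 25L, warn = FALSE)
  first <- first[!startsWith(first, "#") & nzchar(first)]
  if (length(first) && lengths(strsplit(first[1L], "\t"))[1L] == 3L &&
      !grepl("node_a", first[1L], fixed = TRUE)) {
    sif <- read_sif(path)
    return(hin_network(sif[, c("node_a", "node_b")]))
  }
  df <- read_tsv_skip_comments(path)
  if (ncol(df) < 2L) stop_format("HIN file %s needs >= 2 columns", path)
  cols <- if (all(c("node_a", "node_b") %in% names(df)))
    c("node_a", "node_b") else names(df)[1:2]
  hin_network(df[, cols])
}

#' Write / read a clustering as TSV
#'
#' Columns `cluster_id`, `size`, `member_ids` (pipe-separated). The
#' unclustered set is written as a pseudo-row with id `unclustered`.
#' Run metadata (parameters, iterations, convergence) goes to a JSON
#' side-car via [write_cluster_meta()].
#'
#' @param clustering A `dgnet_clustering`.
#' @param path File path.
#' @param seed Optional seed recorded in the header.
#' @return Writers return the path invisibly; `read_clusters()` returns a
#'   list with `clusters` (named list) and `unclustered`.
#' @export
write_clusters <- function(clustering, path, seed = NULL, hash = NULL) {
  stopifnot(inherits(clustering, "dgnet_clustering"))
  df <- data.frame(
    cluster_id = paste0("c", seq_along(clustering$clusters)),
    size = lengths(clustering$clusters),
    member_ids = vapply(clustering$clusters, paste, character(1),
                        collapse = "|"),
    stringsAsFactors = FALSE)
  if (length(clustering$unclustered))
    df <- rbind(df, data.frame(
      cluster_id = "unclustered",
      size = length(clustering$unclustered),
      member_ids = paste(clustering$unclustered, collapse = "|"),
      stringsAsFactors = FALSE))
  write_tsv_with_header(df, path, seed = seed, hash = hash)
}

#' @rdname write_clusters
#' @export
read_clusters <- function(path) {
  df <- read_table_checked(path, c("cluster_id", "size", "member_ids"),
                           "cluster")
  members <- strsplit(as.character(df$member_ids), "|", fixed = TRUE)
  uncl <- df$cluster_id == "unclustered"
  list(clusters = stats::setNames(members[!uncl],
                                  as.character(df$cluster_id[!uncl])),
       unclustered = if (any(uncl)) members[uncl][[1L]] else character(0))
}

#' @rdname write_clusters
#' @export
write_cluster_meta <- function(clustering, path, seed = NULL) {
  stopifnot(inherits(clustering, "dgnet_clustering"))
  meta <- list(version = pkg_version(),
               params = unclass(clustering$params),
               iterations_run = clustering$iterations_run,
               converged = clustering$converged,
               n_clusters = length(clustering$clusters),
               n_unclustered = length(clustering$unclustered),
               seed = seed)
  jsonlite::write_json(meta, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
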