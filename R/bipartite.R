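# Bipartite gene-disease networks: construction from record sets,
# simplification (multi-edge collapse) and degree summaries.

#' Named source presets for network construction
#'
#' `OMIM` is the mendelian-disease source alone; `CURATED` the union of the
#' expert-curated sources (OMIM, UniProt, PharmGKB, CTD); `LHGDN` the
#' text-mining-derived source; `ALL` every source including synthetic.
#'
#' @return Named list of source character vectors.
#' @export
network_presets <- function() {
  list(OMIM = "OMIM",
       CURATED = c("OMIM", "UNIPROT", "PHARMGKB", "CTD"),
       LHGDN = "LHGDN",
       ALL = ASSOC_SOURCES)
}

#' Build a bipartite gene-disease network from association records
#'
#' Genes and diseases form the two vertex classes; edges run only between
#' classes. An edge carries the set of sources reporting the association
#' (the multiplicity of the underlying multigraph). Nodes are induced by
#' edges; records whose source is outside `sources`, and NoAssociation
#' records, are excluded.
#'
#' @param records A `dgnet_associations` data.frame (normally already
#'   passed through [filter_for_analysis()]).
#' @param sources Either a preset name (`"OMIM"`, `"CURATED"`, `"LHGDN"`,
#'   `"ALL"`) or a character vector of sources. An empty set is a
#'   configuration error.
#' @return An object of class `dgnet_bipartite`: list with `genes`,
#'   `diseases`, `edges` (data.frame `gene_id`, `disease_id`, `sources`
#'   list column) and `simplified` flag.
#' @examples
#' rec <- data.frame(gene_id = c("G:1", "G:1"), disease_id = c("D:1", "D:1"),
#'                   source = c("OMIM", "CTD"),
#'                   original_label = c("phenotype", "marker"),
#'                   assoc_type = "Marker", certainty = "Association")
#' rec$evidence <- list(character(0), character(0))
#' net <- build_bipartite(rec, "CURATED")
#' net$edges$sources[[1]]
#' @export
build_bipartite <- function(records, sources = "ALL") {
  presets <- network_presets()
  if (length(sources) == 1L && sources %in% names(presets))
    sources <- presets[[sources]]
  if (!length(sources)) stop_config("empty source set for network construction")
  unknown <- setdiff(sources, ASSOC_SOURCES)
  if (length(unknown)) stop_config("unknown source(s): %s",
                                   paste(unknown, collapse = ", "))
  keep <- records$certainty == "Association" & records$source %in% sources
  rec <- records[keep, , drop = FALSE]
  if (nrow(rec)) {
    key <- paste(rec$gene_id, rec$disease_id, sep = "\r")
    src <- lapply(split(rec$source, key), function(s) sort(unique(s)))
    first <- !duplicated(key)
    edges <- data.frame(gene_id = rec$gene_id[first],
                        disease_id = rec$disease_id[first],
                        stringsAsFactors = FALSE)
    edges$sources <- unname(src[key[first]])
    o <- order(edges$gene_id, edges$disease_id)
    edges <- edges[o, , drop = FALSE]
    rownames(edges) <- NULL
  } else {
    edges <- data.frame(gene_id = character(0), disease_id = character(0),
                        stringsAsFactors = FALSE)
    edges$sources <- list()
  }
  structure(list(genes = sort(unique(edges$gene_id)),
                 diseases = sort(unique(edges$disease_id)),
                 edges = edges,
                 simplified = FALSE),
            class = "dgnet_bipartite")
}

#' Collapse multiple edges to multiplicity one
#'
#' After simplification the source sets are replaced by a single marker so
#' that a node's degree counts its distinct first neighbors, as required
#' before degree summaries and projections. Idempotent; node sets are
#' unchanged.
#'
#' @param net A `dgnet_bipartite` network.
#' @return The simplified network.
#' @export
simplify_bipartite <- function(net) {
  stopifnot(inherits(net, "dgnet_bipartite"))
  net$edges$sources <- rep(list("*"), nrow(net$edges))
  net$simplified <- TRUE
  net
}

#' @export
print.dgnet_bipartite <- function(x, ...) {
  cat(sprintf("bipartite gene-disease network: %d genes, %d diseases, %d edges%s\n",
              length(x$genes), length(x$diseases), nrow(x$edges),
              if (x$simplified) " (simplified)" else ""))
  invisible(x)
}

#' Degree summary of one side of a bipartite network
#'
#' For the disease side the degree is the number of associated genes (the
#' locus heterogeneity of the disease); for the gene side it is the number
#' of associated diseases (the gene's pleiotropy). Reports the degree
#' histogram, mean degree, the two highest-degree nodes (ties broken
#' lexicographically), the number of degree-1 nodes and the size of the
#' largest connected component of the full bipartite graph.
#'
#' @param net A simplified `dgnet_bipartite` network.
#' @param side `"gene"` or `"disease"`.
#' @return List of class `dgnet_degree_summary` with fields `side`,
#'   `degree_histogram` (data.frame `degree`, `count`), `mean_degree`,
#'   `max_degree_nodes`, `n_singletons`, `lcc_size`. An empty network
#'   yields an empty histogram and mean degree 0.
#' @export
degree_summary <- function(net, side = c("gene", "disease")) {
  stopifnot(inherits(net, "dgnet_bipartite"))
  if (!net$simplified) stop_input("degree_summary requires a simplified network")
  side <- match.arg(side)
  ids <- if (side == "gene") net$edges$gene_id else net$edges$disease_id
  if (!length(ids)) {
    return(structure(list(
      side = side,
      degree_histogram = data.frame(degree = integer(0), count = integer(0)),
      mean_degree = 0, max_degree_nodes = character(0),
      n_singletons = 0L, lcc_size = 0L),
      class = "dgnet_degree_summary"))
  }
  deg <- table(ids)
  hist_tab <- table(as.integer(deg))
  histogram <- data.frame(degree = as.integer(names(hist_tab)),
                          count = as.integer(hist_tab))
  o <- order(-as.integer(deg), names(deg))
  top <- names(deg)[o][seq_len(min(2L, length(deg)))]
  g <- igraph::graph_from_data_frame(
    net$edges[, c("gene_id", "disease_id")], directed = FALSE)
  lcc <- max(igraph::components(g)$csize)
  structure(list(side = side,
                 degree_histogram = histogram,
                 mean_degree = mean(as.integer(deg)),
                 max_degree_nodes = top,
                 n_singletons = sum(deg == 1L),
                 lcc_size = as.integer(lcc)),
            class = "dgnet_degree_summary")
}
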