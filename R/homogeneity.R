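# Pathway homogeneity: the maximum fraction of a unit's annotated genes
# sharing one pathway (or GO) annotation. A unit is a single disease (its
# associated genes), a disease cluster (the union of its members' genes)
# or a gene cluster (the member genes themselves). Genes without any
# annotation are excluded from numerator and denominator.

#' Construct a gene-to-pathway annotation map
#'
#' @param gene_to_terms Named list: gene id -> character vector of term
#'   ids. Genes with empty vectors are allowed (unannotated).
#' @param catalog_name Label for the catalog (e.g. the gene-set source).
#' @return Object of class `dgnet_annotation`.
#' @seealso [read_gmt()], [read_annotation_tsv()]
#' @export
annotation_map <- function(gene_to_terms, catalog_name = "catalog") {
  if (is.null(names(gene_to_terms)) ||
      any(!nzchar(names(gene_to_terms))))
    stop_input("gene_to_terms must be a named list with non-empty gene ids")
  gene_to_terms <- lapply(gene_to_terms,
                          function(t) sort(unique(as.character(t))))
  gene_to_terms <- gene_to_terms[order(names(gene_to_terms))]
  if (any(vapply(gene_to_terms, function(t) any(!nzchar(t)), logical(1))))
    stop_input("term ids must be non-empty strings")
  structure(list(gene_to_terms = gene_to_terms,
                 catalog_name = catalog_name),
            class = "dgnet_annotation")
}

#' Annotated genes of a catalog
#' @param ann A `dgnet_annotation`.
#' @return Character vector of gene ids with at least one term.
#' @export
annotated_genes <- function(ann) {
  names(ann$gene_to_terms)[lengths(ann$gene_to_terms) > 0L]
}

#' Pathway homogeneity of one gene set
#'
#' Homogeneity is `max_j n_i^j / n_i`, where `n_i` is the number of unit
#' genes carrying at least one annotation and `n_i^j` the number sharing
#' term `j`. It equals 1 when all annotated genes share a pathway and
#' approaches `1/n_i` when every gene has its own. Undefined (NA) when no
#' unit gene is annotated; such units are skipped downstream rather than
#' aborting.
#'
#' @param genes Character vector of gene ids (a unit).
#' @param ann A `dgnet_annotation`.
#' @param unit_id Optional identifier carried into the result.
#' @return List of class `dgnet_homogeneity` with `unit_id`, `n_total`,
#'   `n_annotated`, `value`, `top_term` (lexicographically smallest
#'   maximizing term; NA when undefined).
#' @examples
#' ann <- annotation_map(list(g1 = "P1", g2 = "P1", g3 = "P2"))
#' pathway_homogeneity(c("g1", "g2", "g3"), ann)$value  # 2/3
#' @export
pathway_homogeneity <- function(genes, ann, unit_id = NA_character_) {
  stopifnot(inherits(ann, "dgnet_annotation"))
  genes <- unique(genes)
  terms <- ann$gene_to_terms[intersect(genes, names(ann$gene_to_terms))]
  terms <- terms[lengths(terms) > 0L]
  n_annotated <- length(terms)
  if (n_annotated == 0L) {
    return(structure(list(unit_id = unit_id, n_total = length(genes),
                          n_annotated = 0L, value = NA_real_,
                          top_term = NA_character_),
                     class = "dgnet_homogeneity"))
  }
  counts <- table(unlist(terms, use.names = FALSE))
  best <- max(counts)
  top <- sort(names(counts)[counts == best])[1L]
  structure(list(unit_id = unit_id, n_total = length(genes),
                 n_annotated = n_annotated,
                 value = as.numeric(best) / n_annotated,
                 top_term = top),
            class = "dgnet_homogeneity")
}

#' Homogeneity of many units at once
#'
#' @param units Named list of gene-id vectors.
#' @param ann A `dgnet_annotation`.
#' @return data.frame with one row per unit: `unit_id`, `n_total`,
#'   `n_annotated`, `value`, `top_term`.
#' @export
homogeneity_table <- function(units, ann) {
  rows <- lapply(names(units), function(u) {
    h <- pathway_homogeneity(units[[u]], ann, unit_id = u)
    data.frame(unit_id = h$unit_id, n_total = h$n_total,
               n_annotated = h$n_annotated, value = h$value,
               top_term = h$top_term, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(unit_id = character(0), n_total = integer(0),
                      n_annotated = integer(0), value = numeric(0),
                      top_term = character(0), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Analysis units from a bipartite network or a clustering
#'
#' `disease_units()` maps each disease to its associated genes (its
#' bipartite neighbors). `cluster_units()` maps each cluster either to the
#' union of its member diseases' gene neighbors (`side = "disease"`) or to
#' the member genes themselves (`side = "gene"`). Duplicate genes across a
#' cluster's diseases are pooled once.
#'
#' @param net A simplified `dgnet_bipartite` network.
#' @return Named list: disease id -> character vector of gene ids.
#' @export
disease_units <- function(net) {
  stopifnot(inherits(net, "dgnet_bipartite"))
  if (!net$simplified) stop_input("disease_units requires a simplified network")
  lapply(split(net$edges$gene_id, net$edges$disease_id), sort)
}

#' @rdname disease_units
#' @param clustering A `dgnet_clustering`.
#' @param side Which projection the clustering came from.
#' @return Named list: cluster id (`"c1"`, `"c2"`, ...) -> gene set.
#' @export
cluster_units <- function(clustering, net = NULL,
                          side = c("disease", "gene")) {
  stopifnot(inherits(clustering, "dgnet_clustering"))
  side <- match.arg(side)
  ids <- paste0("c", seq_along(clustering$clusters))
  if (side == "gene") {
    units <- clustering$clusters
  } else {
    if (is.null(net))
      stop_input("disease-cluster units require the bipartite network")
    if (!net$simplified) stop_input("cluster_units requires a simplified network")
    dmap <- disease_units(net)
    units <- lapply(clustering$clusters, function(members)
      sort(unique(unlist(dmap[intersect(members, names(dmap))]))))
  }
  stats::setNames(units, ids)
}

#' Pearson correlation between homogeneity and unit size
#'
#' Quantifies the decay of homogeneity with increasing locus heterogeneity
#' (unit size counted as annotated genes). Requires at least 3 defined
#' values; zero variance in either coordinate flags the result undefined.
#'
#' @param results data.frame from [homogeneity_table()].
#' @return List with `r`, `n_points`, `defined`.
#' @export
homogeneity_size_correlation <- function(results) {
  ok <- is.finite(results$value)
  x <- results$n_annotated[ok]
  y <- results$value[ok]
  if (length(x) < 3L)
    return(list(r = NA_real_, n_points = length(x), defined = FALSE))
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(r = NA_real_, n_points = length(x), defined = FALSE))
  list(r = stats::cor(x, y), n_points = length(x), defined = TRUE)
}

# ---- fast internal encoding used by the resampling null models ----
# genes become integer indices; each gene's terms become integer term ids.
encode_annotation <- function(ann, genes) {
  terms <- ann$gene_to_terms[genes]
  terms[vapply(terms, is.null, logical(1))] <- list(character(0))
  levels <- sort(unique(unlist(terms, use.names = FALSE)))
  list(term_idx = lapply(terms, function(t) match(t, levels)),
       n_terms = length(levels), genes = genes)
}

# homogeneity value for integer-coded gene indices; NA when unannotated
homog_fast <- function(idx, enc) {
  t <- unlist(enc$term_idx[idx], use.names = FALSE)
  if (!length(t)) return(NA_real_)
  n_ann <- sum(lengths(enc$term_idx[idx]) > 0L)
  max(tabulate(t, nbins = enc$n_terms)) / n_ann
}
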