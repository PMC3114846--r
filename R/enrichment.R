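# Over-representation analysis of cluster gene sets against a pathway/GO
# catalog: one-sided hypergeometric upper-tail p per term, with
# Benjamini-Hochberg q-values over the unit's tested terms.

#' Term over-representation in a gene set
#'
#' For each term annotated to at least one unit gene, tests whether the
#' term is over-represented in the unit relative to the universe with the
#' one-sided hypergeometric upper tail (Fisher's exact test, greater):
#' `p = P[X >= k]` for `X ~ Hypergeom(K, N - K, n)`, where `N` is the
#' annotated universe size, `K` the universe genes carrying the term,
#' `n` the annotated unit genes and `k` the unit genes carrying the term.
#' Unannotated genes are removed from both unit and universe before
#' counting. q-values are Benjamini-Hochberg over the unit's term list.
#' Downstream reports conventionally filter at raw p < 0.05; q is reported
#' alongside.
#'
#' @param genes Character vector of unit gene ids.
#' @param ann A `dgnet_annotation`.
#' @param universe Character vector of background gene ids; must contain
#'   `genes`. Defaults to all annotated genes of the catalog.
#' @param unit_id Optional identifier carried into the result.
#' @return data.frame sorted by ascending p (ties by term id) with columns
#'   `unit_id`, `term_id`, `k`, `K`, `n`, `N`, `p_value`, `q_value`.
#'   Empty when no unit gene is annotated.
#' @export
enrich <- function(genes, ann, universe = NULL, unit_id = NA_character_) {
  stopifnot(inherits(ann, "dgnet_annotation"))
  genes <- unique(genes)
  universe <- unique(universe %||% annotated_genes(ann))
  if (length(setdiff(genes, universe)))
    stop_input("unit contains genes outside the universe")
  universe <- intersect(universe, annotated_genes(ann))
  genes <- intersect(genes, universe)
  empty <- data.frame(unit_id = character(0), term_id = character(0),
                      k = integer(0), K = integer(0), n = integer(0),
                      N = integer(0), p_value = numeric(0),
                      q_value = numeric(0), stringsAsFactors = FALSE)
  if (!length(genes)) return(empty)
  N <- length(universe)
  n <- length(genes)
  uni_terms <- table(unlist(ann$gene_to_terms[universe],
                            use.names = FALSE))
  unit_terms <- table(unlist(ann$gene_to_terms[genes], use.names = FALSE))
  term_id <- names(unit_terms)
  k <- as.integer(unit_terms)
  K <- as.integer(uni_terms[term_id])
  p <- stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
  out <- data.frame(unit_id = unit_id, term_id = term_id, k = k, K = K,
                    n = n, N = N, p_value = p, stringsAsFactors = FALSE)
  out <- out[order(out$p_value, out$term_id), , drop = FALSE]
  out$q_value <- stats::p.adjust(out$p_value, method = "BH")
  rownames(out) <- NULL
  out
}

#' Enrichment over many units
#'
#' @param units Named list of gene-id vectors.
#' @inheritParams enrich
#' @return Row-bound [enrich()] results, one block per unit.
#' @export
enrich_units <- function(units, ann, universe = NULL) {
  out <- do.call(rbind, lapply(names(units), function(u)
    enrich(units[[u]], ann, universe, unit_id = u)))
  if (is.null(out)) out <- enrich(character(0), ann, universe)
  rownames(out) <- NULL
  out
}
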