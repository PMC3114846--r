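# Monopartite projections of the bipartite network with overlap-coefficient
# edge weights: two same-class nodes are joined iff they share a bipartite
# neighbor, and the edge weight is |shared| / min(a_u, a_v), where a_v is
# the node's annotation count (its bipartite degree). The weight lies in
# (0, 1]; it is 1 exactly when the less-annotated node's neighbors are a
# subset of the other's.

#' Project a bipartite network to one vertex class
#'
#' Two nodes of the chosen side are connected if they share at least one
#' neighbor in the bipartite graph. Each projection edge records the shared
#' neighbor set and the overlap-coefficient weight
#' `|shared| / min(a_u, a_v)` where `a_v` is the number of bipartite
#' neighbors of node `v`. Nodes sharing no neighbor are retained as
#' isolated vertices so that downstream cluster statistics can count them.
#'
#' @param net A simplified `dgnet_bipartite` network.
#' @param side `"gene"` or `"disease"`.
#' @return Object of class `dgnet_projection`: list with `side`, `nodes`,
#'   `ann_count` (named integer vector, the `a_v`), and `edges`
#'   (data.frame `node_a`, `node_b`, `shared` list column,
#'   `shared_count`, `weight`; `node_a < node_b` lexicographically).
#' @examples
#' rec <- data.frame(
#'   gene_id = c("G:1", "G:2", "G:2", "G:3"),
#'   disease_id = c("D:1", "D:1", "D:2", "D:2"),
#'   source = "OMIM", original_label = "phenotype",
#'   assoc_type = "Marker", certainty = "Association")
#' rec$evidence <- rep(list(character(0)), 4)
#' p <- project(simplify_bipartite(build_bipartite(rec, "OMIM")), "disease")
#' p$edges  # D:1 and D:2 share G:2, weight 1/min(2, 2)
#' @export
project <- function(net, side = c("gene", "disease")) {
  stopifnot(inherits(net, "dgnet_bipartite"))
  if (!net$simplified) stop_input("project requires a simplified network")
  side <- match.arg(side)
  if (side == "gene") {
    nodes <- net$genes
    own <- net$edges$gene_id
    other <- net$edges$disease_id
  } else {
    nodes <- net$diseases
    own <- net$edges$disease_id
    other <- net$edges$gene_id
  }
  nb <- lapply(split(other, factor(own, levels = nodes)), sort)
  ann_count <- lengths(nb)
  empty_edges <- data.frame(node_a = character(0), node_b = character(0),
                            stringsAsFactors = FALSE)
  empty_edges$shared <- list()
  empty_edges$shared_count <- integer(0)
  empty_edges$weight <- numeric(0)
  if (!length(nodes) || !nrow(net$edges)) {
    return(structure(list(side = side, nodes = nodes,
                          ann_count = ann_count, edges = empty_edges),
                     class = "dgnet_projection"))
  }
  other_ids <- sort(unique(other))
  B <- Matrix::sparseMatrix(i = match(own, nodes),
                            j = match(other, other_ids),
                            x = 1,
                            dims = c(length(nodes), length(other_ids)))
  C <- Matrix::tcrossprod(B)
  C <- Matrix::triu(C, k = 1L)
  tc <- methods::as(methods::as(C, "generalMatrix"), "TsparseMatrix")
  if (!length(tc@x)) {
    return(structure(list(side = side, nodes = nodes,
                          ann_count = ann_count, edges = empty_edges),
                     class = "dgnet_projection"))
  }
  i <- tc@i + 1L
  j <- tc@j + 1L
  cnt <- as.integer(tc@x)
  a <- nodes[i]
  b <- nodes[j]
  swap <- a > b
  tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  o <- order(a, b)
  a <- a[o]; b <- b[o]; cnt <- cnt[o]
  shared <- mapply(function(u, v) intersect(nb[[u]], nb[[v]]),
                   a, b, SIMPLIFY = FALSE, USE.NAMES = FALSE)
  weight <- cnt / pmin(ann_count[a], ann_count[b])
  edges <- data.frame(node_a = a, node_b = b, stringsAsFactors = FALSE)
  edges$shared <- shared
  edges$shared_count <- cnt
  edges$weight <- unname(weight)
  rownames(edges) <- NULL
  structure(list(side = side, nodes = nodes, ann_count = ann_count,
                 edges = edges),
            class = "dgnet_projection")
}

#' @export
print.dgnet_projection <- function(x, ...) {
  cat(sprintf("%s projection: %d nodes, %d weighted edges\n",
              x$side, length(x$nodes), nrow(x$edges)))
  invisible(x)
}
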