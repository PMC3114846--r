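# HINscore: connectivity of a gene cluster inside a reference human
# interaction network (HIN). For a cluster of n genes whose HIN-induced
# subgraph has cc connected components, the score is (n - cc)/(n - 1):
# 1 when the cluster is a single connected component in HIN, 0 when no two
# members interact. Cluster members absent from HIN count as singleton
# components (they contribute n and cc alike).

#' Construct a protein-interaction network
#'
#' Builds a simple undirected graph from an edge table; self-loops are
#' dropped and duplicate/reversed edges collapse to one.
#'
#' @param edges data.frame (or 2-column matrix) whose first two columns
#'   are interacting gene ids.
#' @param nodes Optional additional node ids (genes present in the network
#'   without any interaction).
#' @return Object of class `dgnet_hin`: list with sorted `nodes` and
#'   canonical `edges` (`a < b`).
#' @export
hin_network <- function(edges, nodes = NULL) {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (ncol(edges) < 2L) stop_format("HIN edge table needs two columns")
  a <- as.character(edges[[1L]])
  b <- as.character(edges[[2L]])
  keep <- a != b
  a <- a[keep]; b <- b[keep]
  lo <- pmin(a, b); hi <- pmax(a, b)
  key <- paste(lo, hi, sep = "\r")
  first <- !duplicated(key)
  e <- data.frame(a = lo[first], b = hi[first], stringsAsFactors = FALSE)
  e <- e[order(e$a, e$b), , drop = FALSE]
  rownames(e) <- NULL
  structure(list(nodes = sort(unique(c(e$a, e$b, nodes))), edges = e),
            class = "dgnet_hin")
}

#' @export
print.dgnet_hin <- function(x, ...) {
  cat(sprintf("interaction network: %d nodes, %d edges\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

# precompute integer adjacency restricted to a gene pool (fast null loop)
hin_index <- function(hin, pool) {
  pool <- unique(pool)
  ia <- match(hin$edges$a, pool)
  ib <- match(hin$edges$b, pool)
  keep <- !is.na(ia) & !is.na(ib)
  ia <- ia[keep]; ib <- ib[keep]
  adj <- vector("list", length(pool))
  if (length(ia)) {
    adj_pairs <- split(c(ib, ia), c(ia, ib))
    idx <- as.integer(names(adj_pairs))
    adj[idx] <- adj_pairs
  }
  list(pool = pool, adj = adj)
}

# connected components among `unit` (pool indices) using union-find;
# members without induced edges are singleton components
count_components_idx <- function(unit, idx) {
  k <- length(unit)
  if (k == 0L) return(0L)
  pos <- integer(length(idx$pool))
  pos[unit] <- seq_len(k)
  parent <- seq_len(k)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (i in seq_len(k)) {
    nbs <- idx$adj[[unit[i]]]
    if (is.null(nbs)) next
    js <- pos[nbs]
    js <- js[js > i]
    for (j in js) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[ri] <- rj
    }
  }
  sum(vapply(seq_len(k), function(i) find(i) == i, logical(1)))
}

#' HINscore of a gene set
#'
#' `(n - cc)/(n - 1)` where `n` is the number of genes in the set and `cc`
#' the number of connected components of the subgraph induced on the set by
#' the interaction network. Genes absent from the network are isolated
#' vertices of the subgraph by default (they are genuine cluster members
#' whose interactions are unobserved); `drop_absent` removes them from
#' the computation instead.
#'
#' @param genes Character vector of gene ids.
#' @param hin A `dgnet_hin` network.
#' @param drop_absent Drop genes absent from `hin` before scoring.
#' @return Score in `[0, 1]`, or `NA` when fewer than 2 genes remain.
#' @examples
#' hin <- hin_network(data.frame(a = c("a", "b", "c"), b = c("b", "c", "d")))
#' hin_score(c("a", "b", "c", "d"), hin)  # 1: one connected path
#' @export
hin_score <- function(genes, hin, drop_absent = FALSE) {
  stopifnot(inherits(hin, "dgnet_hin"))
  genes <- unique(genes)
  if (drop_absent) genes <- intersect(genes, hin$nodes)
  n <- length(genes)
  if (n < 2L) return(NA_real_)
  idx <- hin_index(hin, genes)
  cc <- count_components_idx(match(genes, idx$pool), idx)
  (n - cc) / (n - 1)
}
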