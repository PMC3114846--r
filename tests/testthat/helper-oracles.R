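# Independent oracles and tiny fixture builders used across the suite.
# Each oracle is deliberately implemented by a different route than the
# package code it checks (brute-force scans, flood fill, pair counting,
# explicit log-binomial tail sums).

# minimal association record builder
make_records <- function(gene_id, disease_id, source = "OMIM",
                         original_label = "phenotype",
                         certainty = "Association",
                         assoc_type = "Marker",
                         evidence = NULL) {
  n <- max(length(gene_id), length(disease_id))
  df <- data.frame(gene_id = rep_len(gene_id, n),
                   disease_id = rep_len(disease_id, n),
                   source = rep_len(source, n),
                   original_label = rep_len(original_label, n),
                   assoc_type = rep_len(assoc_type, n),
                   certainty = rep_len(certainty, n),
                   stringsAsFactors = FALSE)
  df$evidence <- evidence %||% rep(list(character(0)), n)
  class(df) <- c("dgnet_associations", "data.frame")
  df
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# random bipartite fixture: edge data.frame + records
random_bipartite <- function(n_gene, n_disease, n_edge, seed) {
  set.seed(seed)
  pairs <- expand.grid(g = sprintf("G:%02d", seq_len(n_gene)),
                       d = sprintf("D:%02d", seq_len(n_disease)),
                       stringsAsFactors = FALSE)
  pick <- pairs[sample.int(nrow(pairs), min(n_edge, nrow(pairs))), ]
  make_records(pick$g, pick$d)
}

# brute-force projection: all-pairs common-neighbor scan over adjacency lists
brute_projection <- function(net, side) {
  edges <- net$edges
  if (side == "gene") {
    nb <- split(edges$disease_id, edges$gene_id)
  } else {
    nb <- split(edges$gene_id, edges$disease_id)
  }
  nodes <- sort(names(nb))
  out <- list()
  for (i in seq_along(nodes)) for (j in seq_along(nodes)) {
    if (i >= j) next
    u <- nodes[i]; v <- nodes[j]
    shared <- sort(intersect(nb[[u]], nb[[v]]))
    if (!length(shared)) next
    out[[length(out) + 1L]] <- list(
      node_a = u, node_b = v, shared = shared,
      weight = length(shared) / min(length(unique(nb[[u]])),
                                    length(unique(nb[[v]]))))
  }
  out
}

# flood-fill connected-component count over a node set and an edge table
flood_fill_cc <- function(nodes, edges_a, edges_b) {
  keep <- edges_a %in% nodes & edges_b %in% nodes
  ea <- edges_a[keep]; eb <- edges_b[keep]
  seen <- character(0)
  cc <- 0L
  for (start in nodes) {
    if (start %in% seen) next
    cc <- cc + 1L
    frontier <- start
    while (length(frontier)) {
      seen <- union(seen, frontier)
      nxt <- union(eb[ea %in% frontier], ea[eb %in% frontier])
      frontier <- setdiff(nxt, seen)
    }
  }
  cc
}

# pair-counting ARI: classify every object pair as agreeing or not
ari_pair_oracle <- function(x, y) {
  n <- length(x)
  a <- b <- c_ <- d <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    sx <- x[i] == x[j]; sy <- y[i] == y[j]
    if (sx && sy) a <- a + 1
    else if (sx && !sy) b <- b + 1
    else if (!sx && sy) c_ <- c_ + 1
    else d <- d + 1
  }
  num <- choose(n, 2) * (a + d) - ((a + b) * (a + c_) + (c_ + d) * (b + d))
  den <- choose(n, 2)^2 - ((a + b) * (a + c_) + (c_ + d) * (b + d))
  num / den
}

# exact hypergeometric upper tail via log-binomial sums
exact_hyper_tail <- function(k, K, n, N) {
  x <- seq(max(k, 0L, n + K - N), min(K, n))
  if (!length(x) || k > min(K, n)) return(if (k > min(K, n)) 0 else 1)
  sum(exp(lchoose(K, x) + lchoose(N - K, n - x) - lchoose(N, n)))
}

# direct-formula Pearson correlation
pearson_oracle <- function(x, y) {
  mx <- sum(x) / length(x); my <- sum(y) / length(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}
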