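# Markov Cluster algorithm (MCL) on weighted projection networks.
#
# MCL alternates expansion (matrix powers of a column-stochastic flow
# matrix, simulating random-walk flow) with inflation (elementwise powers
# followed by column renormalization, sharpening flow) until the matrix
# reaches a doubly idempotent limit whose attractor structure defines the
# clusters. Self-loops are added before normalization to damp period-2
# oscillations. The implementation is dense; target networks are at most a
# few thousand nodes.

#' MCL parameters
#'
#' @param inflation Elementwise power applied after expansion; controls
#'   cluster granularity. Must be > 1; default 2.
#' @param expansion Matrix power of the expansion step (>= 2).
#' @param loop_weight Self-loop weight added to every node before
#'   normalization (>= 0).
#' @param prune_threshold Entries below this value are zeroed after each
#'   inflation, then columns are renormalized.
#' @param max_iterations Iteration cap; a run hitting it returns
#'   `converged = FALSE` rather than erroring.
#' @param convergence_tol Maximum absolute entry change defining
#'   convergence.
#' @return List of class `dgnet_mcl_params`.
#' @export
mcl_params <- function(inflation = 2, expansion = 2L, loop_weight = 1,
                       prune_threshold = 1e-5, max_iterations = 200L,
                       convergence_tol = 1e-8) {
  if (!is.numeric(inflation) || inflation <= 1)
    stop_config("MCL inflation must be > 1 (got %s)", format(inflation))
  if (expansion < 2) stop_config("MCL expansion must be >= 2")
  if (loop_weight < 0) stop_config("MCL loop_weight must be >= 0")
  if (prune_threshold < 0) stop_config("MCL prune_threshold must be >= 0")
  if (max_iterations < 1) stop_config("MCL max_iterations must be >= 1")
  if (convergence_tol <= 0) stop_config("MCL convergence_tol must be > 0")
  structure(list(inflation = inflation, expansion = as.integer(expansion),
                 loop_weight = loop_weight,
                 prune_threshold = prune_threshold,
                 max_iterations = as.integer(max_iterations),
                 convergence_tol = convergence_tol),
            class = "dgnet_mcl_params")
}

#' Cluster a weighted projection network with MCL
#'
#' Runs the Markov Cluster iteration on the weighted adjacency matrix of
#' the projection (self-loops of `loop_weight` added, columns normalized to
#' 1) and reads disjoint clusters from the limit matrix: nodes are grouped
#' with the attractors that retain positive mass on them, and attractor
#' systems sharing a node are merged so the result is a partition. Isolated
#' nodes are reported in `unclustered`, not as singleton clusters, and are
#' excluded from cluster statistics. Deterministic for a fixed input.
#'
#' @param net A `dgnet_projection` network.
#' @param params MCL parameters from [mcl_params()].
#' @return Object of class `dgnet_clustering`: list with `clusters`
#'   (list of node-id vectors sorted by decreasing size, ties by smallest
#'   member id), `unclustered`, `params`, `iterations_run`, `converged`,
#'   and `col_dev` (per-iteration maximum deviation of column sums from 1,
#'   a stochasticity diagnostic).
#' @references van Dongen, S. Graph clustering by flow simulation.
#'   PhD thesis, University of Utrecht (2000).
#' @export
mcl <- function(net, params = mcl_params()) {
  stopifnot(inherits(net, "dgnet_projection"))
  stopifnot(inherits(params, "dgnet_mcl_params"))
  nodes <- sort(net$nodes)
  connected <- sort(unique(c(net$edges$node_a, net$edges$node_b)))
  isolated <- setdiff(nodes, connected)
  n <- length(connected)
  if (n == 0L) {
    return(structure(list(clusters = list(), unclustered = isolated,
                          params = params, iterations_run = 0L,
                          converged = TRUE, col_dev = numeric(0)),
                     class = "dgnet_clustering"))
  }
  A <- matrix(0, n, n, dimnames = list(connected, connected))
  ia <- match(net$edges$node_a, connected)
  ib <- match(net$edges$node_b, connected)
  A[cbind(ia, ib)] <- net$edges$weight
  A[cbind(ib, ia)] <- net$edges$weight
  diag(A) <- diag(A) + params$loop_weight
  M <- sweep(A, 2L, colSums(A), "/")
  col_dev <- numeric(0)
  converged <- FALSE
  it <- 0L
  while (it < params$max_iterations) {
    it <- it + 1L
    E <- M
    for (k in seq_len(params$expansion - 1L)) E <- E %*% M
    E <- E^params$inflation
    cs <- colSums(E)
    cs[cs == 0] <- 1
    E <- sweep(E, 2L, cs, "/")
    E[E < params$prune_threshold] <- 0
    cs <- colSums(E)
    cs[cs == 0] <- 1
    E <- sweep(E, 2L, cs, "/")
    col_dev <- c(col_dev, max(abs(colSums(E) - 1)))
    delta <- max(abs(E - M))
    M <- E
    if (delta < params$convergence_tol) {
      converged <- TRUE
      break
    }
  }
  # attractor structure: node j belongs with every node i carrying mass in
  # column j; merging over the symmetrized support yields the partition
  supp <- M > 1e-7
  adj <- supp | t(supp)
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           diag = FALSE)
  memb <- igraph::components(g)$membership
  clusters <- unname(lapply(split(connected, memb), sort))
  min_id <- vapply(clusters, `[`, character(1), 1L)
  o <- order(-lengths(clusters), min_id)
  clusters <- clusters[o]
  structure(list(clusters = clusters, unclustered = isolated,
                 params = params, iterations_run = it,
                 converged = converged, col_dev = col_dev),
            class = "dgnet_clustering")
}

#' @export
print.dgnet_clustering <- function(x, ...) {
  cat(sprintf("MCL clustering: %d clusters over %d nodes (+%d unclustered), %d iterations%s\n",
              length(x$clusters), sum(lengths(x$clusters)),
              length(x$unclustered), x$iterations_run,
              if (x$converged) "" else " [not converged]"))
  invisible(x)
}

#' Adjusted Rand index between two labelings
#'
#' @param x,y Equal-length label vectors over the same objects.
#' @return ARI in `[-1, 1]`; 1 for identical partitions, ~0 for
#'   independent ones.
#' @export
adjusted_rand_index <- function(x, y) {
  if (length(x) != length(y)) stop_input("label vectors differ in length")
  tab <- table(x, y)
  comb2 <- function(v) sum(v * (v - 1) / 2)
  sum_ij <- comb2(as.vector(tab))
  sum_a <- comb2(rowSums(tab))
  sum_b <- comb2(colSums(tab))
  n2 <- comb2(sum(tab))
  expected <- sum_a * sum_b / n2
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == expected)  # both partitions trivial: agree iff identical
    return(if (sum_ij == max_idx) 1 else 0)
  (sum_ij - expected) / (max_idx - expected)
}

#' Recovery of a planted partition by a clustering
#'
#' Compares an MCL clustering against known ground-truth block labels with
#' the adjusted Rand index. Unclustered nodes enter as singletons. Every
#' node in the clustering must carry a truth label.
#'
#' @param clustering A `dgnet_clustering`.
#' @param truth Named vector mapping node id to block id.
#' @return ARI in `[-1, 1]`.
#' @export
planted_partition_recovery <- function(clustering, truth) {
  stopifnot(inherits(clustering, "dgnet_clustering"))
  nodes <- c(unlist(clustering$clusters), clustering$unclustered)
  missing <- setdiff(nodes, names(truth))
  if (length(missing))
    stop_input("node(s) without truth label: %s",
               paste(utils::head(missing, 3), collapse = ", "))
  labels <- c(rep(seq_along(clustering$clusters),
                  lengths(clustering$clusters)),
              seq_along(clustering$unclustered) +
                length(clustering$clusters) + 1e6)
  adjusted_rand_index(labels, unname(truth[nodes]))
}
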