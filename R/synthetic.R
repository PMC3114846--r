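# Synthetic gene-disease data with planted pathway structure.
#
# Genes are partitioned into K pathways (their home pathway = primary
# annotation); each disease has a home pathway and draws its m_d genes
# from it with probability pi (the planted modularity), otherwise
# uniformly from all other genes. Locus heterogeneity m_d follows a
# heavy-tailed truncated power law (1 + zeta-like tail), so diseases span
# the few-gene to many-gene range. Each association is reported by a
# random subset of sources (at least one), emulating the small overlap
# between curated databases; a surrogate interaction network connects
# within-pathway gene pairs with probability hin_p_in and cross-pathway
# pairs with hin_p_out. Ground truth (every gene's and disease's home
# pathway) is returned for validation.

#' Configuration of the synthetic generator
#'
#' @param n_pathways Number of planted pathways K.
#' @param genes_per_pathway Genes per pathway: a single size shared by all
#'   pathways or a length-K vector of per-pathway sizes.
#' @param n_diseases Number of diseases D.
#' @param het_alpha Power-law exponent of the locus-heterogeneity law:
#'   `P(m = 1 + z)` proportional to `z^-het_alpha` for
#'   `z = 1 .. het_max - 1`.
#' @param het_max Maximum genes per disease; must not exceed the total
#'   gene count.
#' @param modularity pi in `[0, 1]`: probability that a disease gene is
#'   drawn from the disease's home pathway.
#' @param multi_annotation_rate q in `[0, 1]`: probability that a gene is
#'   annotated to a second, random pathway.
#' @param hin_p_in,hin_p_out Interaction probability for within-pathway /
#'   cross-pathway gene pairs.
#' @param source_profile Named inclusion probabilities per source; each
#'   source reports an association independently with its probability, and
#'   at least one source is forced by rejection sampling.
#' @param seed Integer seed; the whole generation is reproducible from it.
#' @return List of class `dgnet_synth_config`.
#' @export
synth_config <- function(n_pathways = 10L, genes_per_pathway = 30L,
                         n_diseases = 300L, het_alpha = 1.5,
                         het_max = 100L, modularity = 0.7,
                         multi_annotation_rate = 0.1,
                         hin_p_in = 0.3, hin_p_out = 0.005,
                         source_profile = c(OMIM = 0.2, UNIPROT = 0.15,
                                            PHARMGKB = 0.1, CTD = 0.35,
                                            LHGDN = 0.5),
                         seed = 1L) {
  if (n_pathways < 1 || any(genes_per_pathway < 1) || n_diseases < 1)
    stop_config("n_pathways, genes_per_pathway and n_diseases must be >= 1")
  if (!length(genes_per_pathway) %in% c(1L, n_pathways))
    stop_config("genes_per_pathway must be a scalar or one size per pathway")
  if (het_max < 2 || het_alpha <= 0)
    stop_config("het_max must be >= 2 and het_alpha > 0")
  probs <- c(modularity, multi_annotation_rate, hin_p_in, hin_p_out,
             source_profile)
  if (any(probs < 0 | probs > 1))
    stop_config("probabilities must lie in [0, 1]")
  if (is.null(names(source_profile)) ||
      !all(names(source_profile) %in% ASSOC_SOURCES))
    stop_config("source_profile must be named with known sources")
  structure(list(n_pathways = as.integer(n_pathways),
                 genes_per_pathway = as.integer(
                   rep_len(genes_per_pathway, n_pathways)),
                 n_diseases = as.integer(n_diseases),
                 het_alpha = het_alpha, het_max = as.integer(het_max),
                 modularity = modularity,
                 multi_annotation_rate = multi_annotation_rate,
                 hin_p_in = hin_p_in, hin_p_out = hin_p_out,
                 source_profile = source_profile,
                 seed = as.integer(seed)),
            class = "dgnet_synth_config")
}

# map each source to the original_label its records carry; the first four
# use the source's native vocabulary, text-mining and synthetic records
# use the ontology class-name pass-through
SYNTH_LABELS <- c(OMIM = "phenotype", UNIPROT = "disease_variant",
                  PHARMGKB = "Related", CTD = "marker", LHGDN = "Marker",
                  SYNTH = "Marker")

#' Generate a synthetic gene-disease dataset with known ground truth
#'
#' @param config A [synth_config()].
#' @return List of class `dgnet_synth` with components `records`
#'   (a `dgnet_associations` data.frame), `annotation`
#'   (a `dgnet_annotation`), `hin` (a `dgnet_hin`), and `truth` (list
#'   with `gene_home_pathway`, `disease_home_pathway`, `config`).
#' @examples
#' syn <- generate_synth(synth_config(n_pathways = 3, genes_per_pathway = 8,
#'                                    n_diseases = 12, het_max = 6, seed = 7))
#' length(syn$truth$gene_home_pathway)
#' @export
generate_synth <- function(config) {
  stopifnot(inherits(config, "dgnet_synth_config"))
  K <- config$n_pathways
  G <- config$genes_per_pathway
  D <- config$n_diseases
  n_genes <- sum(G)
  if (config$het_max > n_genes)
    stop_config("het_max (%d) exceeds the total gene count (%d)",
                config$het_max, n_genes)
  with_seed(config$seed, {
    genes <- sprintf("G:%04d", seq_len(n_genes))
    pathways <- sprintf("PW%02d", seq_len(K))
    gene_home <- stats::setNames(rep(pathways, times = G), genes)
    # annotation: home pathway plus, with rate q, one other random pathway
    extra <- stats::runif(n_genes) < config$multi_annotation_rate
    gene_terms <- as.list(unname(gene_home))
    if (K > 1L) {
      for (i in which(extra)) {
        others <- setdiff(pathways, gene_home[i])
        gene_terms[[i]] <- c(gene_terms[[i]], sample(others, 1L))
      }
    }
    names(gene_terms) <- genes
    # diseases: balanced (round-robin) home pathways, heavy-tailed sizes
    diseases <- sprintf("D:%04d", seq_len(D))
    disease_home <- stats::setNames(rep_len(pathways, D), diseases)
    z_max <- config$het_max - 1L
    zp <- (seq_len(z_max))^(-config$het_alpha)
    m <- 1L + sample.int(z_max, D, replace = TRUE, prob = zp)
    home_genes <- split(genes, unname(gene_home))
    assoc_g <- vector("list", D)
    for (d in seq_len(D)) {
      hg <- home_genes[[disease_home[d]]]
      og <- setdiff(genes, hg)
      n_home <- stats::rbinom(1L, m[d], config$modularity)
      n_home <- min(n_home, length(hg))
      n_other <- min(m[d] - n_home, length(og))
      n_home <- min(m[d] - n_other, length(hg))
      assoc_g[[d]] <- c(if (n_home > 0L) sample(hg, n_home),
                        if (n_other > 0L) sample(og, n_other))
    }
    gd_gene <- unlist(assoc_g, use.names = FALSE)
    gd_disease <- rep(diseases, lengths(assoc_g))
    # sources: independent inclusion, at least one forced by rejection
    prof <- config$source_profile
    ns <- length(prof)
    pick_sources <- function() {
      repeat {
        inc <- stats::runif(ns) < prof
        if (any(inc)) return(names(prof)[inc])
      }
    }
    src_sets <- replicate(length(gd_gene), pick_sources(), simplify = FALSE)
    rec <- data.frame(
      gene_id = rep(gd_gene, lengths(src_sets)),
      disease_id = rep(gd_disease, lengths(src_sets)),
      source = unlist(src_sets, use.names = FALSE),
      stringsAsFactors = FALSE)
    rec$original_label <- unname(SYNTH_LABELS[rec$source])
    res <- resolve_labels(rec$source, rec$original_label,
                          default_label_map())
    rec$assoc_type <- res$assoc_type
    rec$certainty <- res$certainty
    rec$evidence <- rep(list(character(0)), nrow(rec))
    records <- new_associations(rec)
    # surrogate interaction network: modular random graph over the genes
    pair_i <- rep(seq_len(n_genes - 1L),
                  times = (n_genes - 1L):1L)
    pair_j <- unlist(lapply(seq_len(n_genes - 1L),
                            function(i) (i + 1L):n_genes),
                     use.names = FALSE)
    same <- gene_home[pair_i] == gene_home[pair_j]
    p_edge <- ifelse(same, config$hin_p_in, config$hin_p_out)
    on <- stats::runif(length(p_edge)) < p_edge
    hin <- hin_network(data.frame(a = genes[pair_i[on]],
                                  b = genes[pair_j[on]],
                                  stringsAsFactors = FALSE),
                       nodes = genes)
    structure(list(records = records,
                   annotation = annotation_map(gene_terms,
                                               "synthetic_pathways"),
                   hin = hin,
                   truth = list(gene_home_pathway = gene_home,
                                disease_home_pathway = disease_home,
                                config = config)),
              class = "dgnet_synth")
  })
}

#' Sweep the planted modularity and measure recovery statistics
#'
#' For each value of pi on the grid and each replicate (with a seed derived
#' from `seed`), generates a dataset, builds and simplifies the ALL
#' network, and records the mean disease pathway homogeneity and the mean
#' HINscore of the pathway-true gene clusters (genes grouped by their home
#' pathway).
#'
#' @param config Base [synth_config()]; its `modularity` and `seed` are
#'   overridden per grid point / replicate.
#' @param pi_grid Ordered vector of pi values in `[0, 1]`.
#' @param replicates Replicates per grid point (>= 1).
#' @param seed Master seed for deriving per-replicate seeds.
#' @return data.frame `pi`, `mean_homogeneity`, `mean_hinscore`.
#' @export
sweep_modularity <- function(config, pi_grid, replicates = 3L, seed = 1L) {
  stopifnot(inherits(config, "dgnet_synth_config"))
  if (!length(pi_grid)) stop_config("empty modularity grid")
  if (any(pi_grid < 0 | pi_grid > 1))
    stop_config("pi values must lie in [0, 1]")
  if (replicates < 1) stop_config("replicates must be >= 1")
  rows <- lapply(seq_along(pi_grid), function(gi) {
    hom <- hs <- numeric(replicates)
    for (r in seq_len(replicates)) {
      cfg <- config
      cfg$modularity <- pi_grid[gi]
      cfg$seed <- derive_seed(seed, (gi - 1L) * replicates + r)
      syn <- generate_synth(cfg)
      net <- simplify_bipartite(
        build_bipartite(filter_for_analysis(syn$records), "ALL"))
      ht <- homogeneity_table(disease_units(net), syn$annotation)
      hom[r] <- mean(ht$value, na.rm = TRUE)
      gclust <- split(names(syn$truth$gene_home_pathway),
                      unname(syn$truth$gene_home_pathway))
      hs[r] <- mean(vapply(gclust, hin_score, numeric(1), hin = syn$hin),
                    na.rm = TRUE)
    }
    data.frame(pi = pi_grid[gi], mean_homogeneity = mean(hom),
               mean_hinscore = mean(hs))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
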