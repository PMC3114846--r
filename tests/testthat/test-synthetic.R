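small_cfg <- function(seed = 5, ...) {
  synth_config(n_pathways = 3, genes_per_pathway = 10, n_diseases = 12,
               het_max = 6, seed = seed, ...)
}

test_that("generation is byte-identical for identical config and seed", {
  s1 <- generate_synth(small_cfg())
  s2 <- generate_synth(small_cfg())
  expect_identical(s1, s2)
  s3 <- generate_synth(small_cfg(seed = 6))
  expect_false(identical(s1$records, s3$records))
})

test_that("every gene and disease carries a home-pathway truth label", {
  syn <- generate_synth(small_cfg())
  expect_length(syn$truth$gene_home_pathway, 30L)
  expect_length(syn$truth$disease_home_pathway, 12L)
  expect_setequal(unique(syn$truth$gene_home_pathway),
                  paste0("PW0", 1:3))
})

test_that("full modularity without multi-annotation forces homogeneity 1", {
  cfg <- synth_config(n_pathways = 3, genes_per_pathway = 10,
                      n_diseases = 9, het_alpha = 0.1, het_max = 5,
                      modularity = 1, multi_annotation_rate = 0,
                      seed = 2)
  syn <- generate_synth(cfg)
  net <- simplify_bipartite(build_bipartite(
    filter_for_analysis(syn$records), "ALL"))
  ht <- homogeneity_table(disease_units(net), syn$annotation)
  expect_true(all(ht$value == 1))
})

test_that("deterministic interaction regimes give extreme HINscores", {
  cfg <- small_cfg(hin_p_in = 1, hin_p_out = 0,
                   multi_annotation_rate = 0)
  syn <- generate_synth(cfg)
  clusters <- split(names(syn$truth$gene_home_pathway),
                    unname(syn$truth$gene_home_pathway))
  for (cl in clusters) expect_equal(hin_score(cl, syn$hin), 1)
})

test_that("impossible configurations error before generation", {
  expect_error(generate_synth(synth_config(n_pathways = 2,
                                           genes_per_pathway = 3,
                                           het_max = 10)),
               class = "dgnet_config_error")
  expect_error(synth_config(modularity = 1.5),
               class = "dgnet_config_error")
  expect_error(synth_config(genes_per_pathway = c(5, 5),
                            n_pathways = 3),
               class = "dgnet_config_error")
})

test_that("locus-heterogeneity marginals match the configured law", {
  cfg <- synth_config(n_pathways = 10, genes_per_pathway = 30,
                      n_diseases = 2000, het_alpha = 1.5, het_max = 12,
                      seed = 10)
  syn <- generate_synth(cfg)
  net <- simplify_bipartite(build_bipartite(
    filter_for_analysis(syn$records), "ALL"))
  m <- lengths(disease_units(net))
  z <- 1:11
  p_theory <- z^(-1.5) / sum(z^(-1.5))
  obs <- tabulate(factor(m - 1L, levels = z))
  gof <- suppressWarnings(chisq.test(obs, p = p_theory))
  expect_gt(gof$p.value, 0.01)
})

test_that("pairwise source co-occurrence matches the at-least-one-renormalized product", {
  prof <- c(OMIM = 0.3, CTD = 0.4, LHGDN = 0.5)
  cfg <- synth_config(n_pathways = 5, genes_per_pathway = 20,
                      n_diseases = 1200, het_alpha = 0.5, het_max = 8,
                      source_profile = prof, seed = 20)
  syn <- generate_synth(cfg)
  rec <- syn$records
  key <- paste(rec$gene_id, rec$disease_id)
  n_assoc <- length(unique(key))
  # P(both | at least one source) = p1 p2 / (1 - prod(1 - p))
  p_none <- prod(1 - prof)
  for (pair in list(c("OMIM", "CTD"), c("CTD", "LHGDN"))) {
    has1 <- unique(key[rec$source == pair[1]])
    has2 <- unique(key[rec$source == pair[2]])
    obs <- length(intersect(has1, has2)) / n_assoc
    expected <- prof[[pair[1]]] * prof[[pair[2]]] / (1 - p_none)
    se <- sqrt(expected * (1 - expected) / n_assoc)
    expect_lt(abs(obs - expected), 3 * se + 1e-9)
  }
})

test_that("modularity sweep endpoints and input validation behave", {
  cfg <- synth_config(n_pathways = 4, genes_per_pathway = 12,
                      n_diseases = 30, het_alpha = 0.3, het_max = 8,
                      multi_annotation_rate = 0)
  tab <- sweep_modularity(cfg, c(0, 1), replicates = 2, seed = 3)
  expect_equal(tab$pi, c(0, 1))
  expect_gt(tab$mean_homogeneity[2], tab$mean_homogeneity[1])
  expect_error(sweep_modularity(cfg, numeric(0)),
               class = "dgnet_config_error")
  expect_error(sweep_modularity(cfg, c(0, 1), replicates = 0),
               class = "dgnet_config_error")
})
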