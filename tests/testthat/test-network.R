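test_that("bipartite edges union their sources and presets select them", {
  rec <- make_records(c("g1", "g1"), c("d1", "d1"),
                      source = c("OMIM", "CTD"),
                      original_label = c("phenotype", "marker"))
  net <- build_bipartite(rec, "CURATED")
  expect_equal(nrow(net$edges), 1L)
  expect_equal(net$edges$sources[[1]], c("CTD", "OMIM"))
  empty <- build_bipartite(rec, "LHGDN")
  expect_equal(nrow(empty$edges), 0L)
  expect_length(empty$genes, 0L)
  tri <- make_records(c("g1", "g1", "g2"), c("d1", "d2", "d2"))
  net3 <- build_bipartite(tri, "OMIM")
  expect_equal(nrow(net3$edges), 3L)
  expect_length(net3$genes, 2L)
  expect_length(net3$diseases, 2L)
  expect_error(build_bipartite(rec, character(0)),
               class = "dgnet_config_error")
})

test_that("simplification collapses multiplicity and is idempotent", {
  rec <- make_records(rep("g1", 3), rep("d1", 3),
                      source = c("OMIM", "CTD", "UNIPROT"),
                      original_label = c("phenotype", "marker",
                                         "disease_variant"),
                      assoc_type = c("Marker", "Marker",
                                     "GeneticVariation"))
  net <- simplify_bipartite(build_bipartite(rec, "ALL"))
  expect_equal(lengths(net$edges$sources), 1L)
  expect_identical(simplify_bipartite(net)$edges, net$edges)
  expect_identical(net$genes, "g1")
})

test_that("node degree after simplify equals the brute-force distinct-neighbor count", {
  rec <- random_bipartite(6, 5, 10, seed = 42)
  net <- simplify_bipartite(build_bipartite(rec, "ALL"))
  for (d in net$diseases) {
    brute <- length(unique(rec$gene_id[rec$disease_id == d]))
    expect_equal(sum(net$edges$disease_id == d), brute)
  }
})

test_that("projection weights follow the overlap coefficient", {
  rec <- make_records(c("g1", "g2", "g2", "g3", "g4"),
                      c("d1", "d1", "d2", "d2", "d2"))
  p <- project(simplify_bipartite(build_bipartite(rec, "ALL")), "disease")
  expect_equal(nrow(p$edges), 1L)
  expect_equal(p$edges$shared[[1]], "g2")
  expect_equal(p$edges$weight, 1 / min(2, 3))
  # subset annotation: the less-annotated node shares everything -> weight 1
  rec2 <- make_records(c("g1", "g2", "g1", "g2", "g3"),
                       c("d1", "d1", "d2", "d2", "d2"))
  p2 <- project(simplify_bipartite(build_bipartite(rec2, "ALL")), "disease")
  expect_equal(p2$edges$weight, 1)
  # disjoint diseases share nothing
  rec3 <- make_records(c("g1", "g2"), c("d1", "d2"))
  p3 <- project(simplify_bipartite(build_bipartite(rec3, "ALL")), "disease")
  expect_equal(nrow(p3$edges), 0L)
  expect_setequal(p3$nodes, c("d1", "d2"))  # isolated nodes retained
})

test_that("projection matches the brute-force common-neighbor scan on random graphs", {
  for (seed in 1:20) {
    rec <- random_bipartite(8, 7, 18, seed = seed)
    net <- simplify_bipartite(build_bipartite(rec, "ALL"))
    for (side in c("gene", "disease")) {
      p <- project(net, side)
      oracle <- brute_projection(net, side)
      expect_equal(nrow(p$edges), length(oracle))
      for (i in seq_along(oracle)) {
        expect_equal(p$edges$node_a[i], oracle[[i]]$node_a)
        expect_equal(p$edges$node_b[i], oracle[[i]]$node_b)
        expect_equal(p$edges$shared[[i]], oracle[[i]]$shared)
        expect_equal(p$edges$weight[i], oracle[[i]]$weight)
      }
      expect_true(all(p$edges$weight > 0 & p$edges$weight <= 1))
    }
  }
})

test_that("weight is 1 exactly when the smaller neighbor set is nested in the larger", {
  for (seed in 21:30) {
    rec <- random_bipartite(7, 6, 14, seed = seed)
    net <- simplify_bipartite(build_bipartite(rec, "ALL"))
    p <- project(net, "disease")
    nb <- split(net$edges$gene_id, net$edges$disease_id)
    for (i in seq_len(nrow(p$edges))) {
      u <- nb[[p$edges$node_a[i]]]; v <- nb[[p$edges$node_b[i]]]
      small <- if (length(u) <= length(v)) u else v
      big <- if (length(u) <= length(v)) v else u
      expect_equal(p$edges$weight[i] == 1, all(small %in% big))
    }
  }
})

test_that("adding an association never removes a projection edge nor shrinks shared sets", {
  rec <- random_bipartite(6, 6, 12, seed = 99)
  net1 <- simplify_bipartite(build_bipartite(rec, "ALL"))
  p1 <- project(net1, "disease")
  extra <- make_records("G:01", "D:05")
  rec2 <- rbind(rec, extra)
  class(rec2) <- class(rec)
  p2 <- project(simplify_bipartite(build_bipartite(rec2, "ALL")), "disease")
  key1 <- paste(p1$edges$node_a, p1$edges$node_b)
  key2 <- paste(p2$edges$node_a, p2$edges$node_b)
  expect_true(all(key1 %in% key2))
  for (i in seq_along(key1)) {
    j <- match(key1[i], key2)
    expect_gte(p2$edges$shared_count[j], p1$edges$shared_count[i])
  }
})

test_that("degree summaries match direct tallies and handle degenerate inputs", {
  star <- make_records(sprintf("g%d", 1:5), "d1")
  net <- simplify_bipartite(build_bipartite(star, "ALL"))
  ds <- degree_summary(net, "disease")
  gs <- degree_summary(net, "gene")
  expect_equal(ds$mean_degree, 5)
  expect_equal(gs$mean_degree, 1)
  expect_equal(ds$lcc_size, 6L)
  expect_equal(gs$n_singletons, 5L)
  empty <- simplify_bipartite(build_bipartite(star[0, ], "ALL"))
  es <- degree_summary(empty, "disease")
  expect_equal(es$mean_degree, 0)
  expect_equal(nrow(es$degree_histogram), 0L)
  rec <- random_bipartite(8, 8, 20, seed = 5)
  net2 <- simplify_bipartite(build_bipartite(rec, "ALL"))
  s <- degree_summary(net2, "gene")
  # independent tally: distinct diseases per gene, then histogram of counts
  per_gene <- vapply(net2$genes, function(g)
    length(unique(rec$disease_id[rec$gene_id == g])), integer(1))
  tally <- table(per_gene)
  expect_equal(s$degree_histogram$count,
               as.integer(tally[as.character(s$degree_histogram$degree)]))
  expect_equal(sum(s$degree_histogram$count), length(net2$genes))
})
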