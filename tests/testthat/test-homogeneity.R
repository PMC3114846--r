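test_that("pathway homogeneity follows its definition on small units", {
  ann <- annotation_map(list(g1 = "P1", g2 = "P1", g3 = "P1"))
  expect_equal(pathway_homogeneity(c("g1", "g2", "g3"), ann)$value, 1)
  ann2 <- annotation_map(list(g1 = "P1", g2 = "P1", g3 = "P2"))
  h <- pathway_homogeneity(c("g1", "g2", "g3"), ann2)
  expect_equal(h$value, 2 / 3)
  expect_equal(h$top_term, "P1")
  # unannotated genes are excluded from numerator and denominator
  ann3 <- annotation_map(list(g1 = "P1", g2 = character(0), g3 = "P1"))
  h3 <- pathway_homogeneity(c("g1", "g2", "g3"), ann3)
  expect_equal(h3$n_annotated, 2L)
  expect_equal(h3$value, 1)
  # no annotated gene: undefined, not an error
  h0 <- pathway_homogeneity("g2", ann3)
  expect_true(is.na(h0$value))
  expect_equal(h0$n_annotated, 0L)
})

test_that("homogeneity ignores gene order and term-free catalog padding", {
  ann <- annotation_map(list(g1 = c("P1", "P2"), g2 = "P1", g3 = "P3"))
  u <- c("g1", "g2", "g3")
  base <- pathway_homogeneity(u, ann)
  expect_equal(pathway_homogeneity(rev(u), ann)$value, base$value)
  padded <- annotation_map(c(ann$gene_to_terms,
                             list(zz1 = character(0), zz2 = character(0))))
  expect_equal(pathway_homogeneity(u, padded)$value, base$value)
})

test_that("tie on the top term breaks lexicographically", {
  ann <- annotation_map(list(g1 = "PB", g2 = "PB", g3 = "PA", g4 = "PA"))
  expect_equal(pathway_homogeneity(paste0("g", 1:4), ann)$top_term, "PA")
})

test_that("disease and cluster units collect the right gene sets", {
  rec <- make_records(c("g1", "g2", "g2", "g3"),
                      c("d1", "d1", "d2", "d2"))
  net <- simplify_bipartite(build_bipartite(rec, "ALL"))
  du <- disease_units(net)
  expect_equal(du$d1, c("g1", "g2"))
  expect_equal(du$d2, c("g2", "g3"))
  cl <- structure(list(clusters = list(c("d1", "d2")),
                       unclustered = character(0)),
                  class = "dgnet_clustering")
  cu <- cluster_units(cl, net, "disease")
  expect_equal(cu$c1, c("g1", "g2", "g3"))  # union with dedup
  gcl <- structure(list(clusters = list(c("g1", "g2")),
                        unclustered = character(0)),
                   class = "dgnet_clustering")
  expect_equal(cluster_units(gcl, side = "gene")$c1, c("g1", "g2"))
})

test_that("HINscore endpoints and the component-count formula are exact", {
  hin <- hin_network(data.frame(a = c("a", "b", "c"),
                                b = c("b", "c", "d")))
  expect_equal(hin_score(c("a", "b", "c", "d"), hin), 1)
  none <- hin_network(data.frame(a = "x", b = "y"),
                      nodes = c("a", "b", "c", "d"))
  expect_equal(hin_score(c("a", "b", "c", "d"), none), 0)
  two <- hin_network(data.frame(a = c("a", "c"), b = c("b", "d")))
  expect_equal(hin_score(c("a", "b", "c", "d"), two), (4 - 2) / (4 - 1))
  expect_true(is.na(hin_score("a", hin)))
})

test_that("HINscore component counts match a flood-fill oracle on random graphs", {
  set.seed(12)
  for (i in 1:15) {
    genes <- sprintf("g%02d", 1:12)
    ne <- sample(3:20, 1)
    ea <- sample(genes, ne, replace = TRUE)
    eb <- sample(genes, ne, replace = TRUE)
    keep <- ea != eb
    hin <- hin_network(data.frame(a = ea[keep], b = eb[keep]),
                       nodes = genes)
    unit <- sample(genes, sample(2:12, 1))
    cc <- flood_fill_cc(unit, hin$edges$a, hin$edges$b)
    n <- length(unit)
    expect_equal(hin_score(unit, hin), (n - cc) / (n - 1))
    expect_equal(hin_score(unit, hin), 1 - (cc - 1) / (n - 1))
  }
})

test_that("HINscore is monotone under edge addition and ignores outside edges", {
  genes <- c("a", "b", "c", "d", "e")
  base <- data.frame(a = "a", b = "b")
  unit <- c("a", "b", "c", "d")
  s0 <- hin_score(unit, hin_network(base, nodes = genes))
  s1 <- hin_score(unit, hin_network(rbind(base,
                                          data.frame(a = "c", b = "d")),
                                    nodes = genes))
  expect_gte(s1, s0)
  outside <- rbind(base, data.frame(a = "e", b = "a"))
  # edge to a node outside the unit changes nothing inside it
  expect_equal(hin_score(unit, hin_network(base, nodes = genes)),
               hin_score(unit, hin_network(outside, nodes = genes)))
})

test_that("homogeneity-size correlation matches the direct formula and flags degeneracy", {
  set.seed(4)
  tab <- data.frame(value = runif(20),
                    n_annotated = sample(2:40, 20, replace = TRUE))
  r <- homogeneity_size_correlation(tab)
  expect_true(r$defined)
  expect_equal(r$r, pearson_oracle(tab$n_annotated, tab$value))
  # strictly decreasing in size -> negative
  dec <- data.frame(value = seq(1, 0.1, length.out = 10),
                    n_annotated = 1:10)
  expect_lt(homogeneity_size_correlation(dec)$r, 0)
  const <- data.frame(value = rep(0.5, 5), n_annotated = 1:5)
  expect_false(homogeneity_size_correlation(const)$defined)
  expect_false(homogeneity_size_correlation(dec[1:2, ])$defined)
})
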