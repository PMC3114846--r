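test_that("bin validation rejects overlaps and binned means match a group-by oracle", {
  expect_error(dgnet:::validate_bins(data.frame(lo = c(2, 4), hi = c(5, 8))),
               class = "dgnet_config_error")
  # default bins: 2-5 holds sizes 2,3,4
  out <- bin_by_size(c(2, 3, 4), c(1, 1, 1))
  expect_equal(out$label, "2-5")
  expect_equal(out$mean, 1)
  expect_equal(out$n, 3L)
  # empty bins are absent
  expect_false(">100" %in% out$label)
  set.seed(9)
  sizes <- sample(2:120, 50, replace = TRUE)
  vals <- runif(50)
  res <- bin_by_size(sizes, vals)
  bins <- default_bins()
  for (i in seq_len(nrow(res))) {
    sel <- sizes >= res$lo[i] & sizes <= res$hi[i]
    expect_equal(res$mean[i], sum(vals[sel]) / sum(sel))
    expect_equal(res$n[i], sum(sel))
    if (res$n[i] >= 2) {
      m <- mean(vals[sel]); s <- sd(vals[sel]); n <- sum(sel)
      expect_equal(res$ci_hi[i], m + qt(0.975, n - 1) * s / sqrt(n))
    }
  }
  expect_equal(sum(res$n), 50L)
})

test_that("degenerate single-term annotation forces null homogeneity 1 and p = 1", {
  genes <- sprintf("g%d", 1:20)
  ann <- annotation_map(setNames(as.list(rep("P1", 20)), genes))
  units <- list(u1 = genes[1:3], u2 = genes[4:9])
  ns <- null_homogeneity(units, "sample_genes", ann, pool = genes,
                         n_resamples = 50, seed = 1)
  expect_true(all(ns$per_bin$null_mean == 1))
  expect_true(all(ns$per_bin$real_mean == 1))
  expect_true(all(ns$per_bin$p_empirical == 1))
})

test_that("null model configuration errors are raised before sampling", {
  ann <- annotation_map(list(g1 = "P1", g2 = "P1", g3 = "P2"))
  units <- list(u1 = c("g1", "g2"))
  expect_error(null_homogeneity(units, "sample_genes", ann,
                                pool = c("g1", "g2", "g3"),
                                n_resamples = 0),
               class = "dgnet_config_error")
  # unit larger than the pool names the unit
  big <- list(uX = c("g1", "g2", "g3"))
  expect_error(null_homogeneity(big, "sample_genes", ann,
                                pool = c("g1", "g2"), n_resamples = 10),
               "uX", class = "dgnet_input_error")
})

test_that("null summaries are reproducible from the seed and record it", {
  set.seed(999)  # outer RNG state must not leak in
  genes <- sprintf("g%d", 1:30)
  ann <- annotation_map(setNames(as.list(sample(paste0("P", 1:5), 30,
                                                replace = TRUE)), genes))
  units <- list(a = genes[1:4], b = genes[5:10], c = genes[11:13])
  n1 <- null_homogeneity(units, "sample_genes", ann, pool = genes,
                         n_resamples = 40, seed = 7)
  n2 <- null_homogeneity(units, "sample_genes", ann, pool = genes,
                         n_resamples = 40, seed = 7)
  expect_identical(n1$per_bin, n2$per_bin)
  expect_equal(n1$seed, 7)
  n3 <- null_homogeneity(units, "sample_genes", ann, pool = genes,
                         n_resamples = 40, seed = 8)
  expect_false(identical(n1$per_bin$null_mean, n3$per_bin$null_mean))
})

test_that("cluster-shuffle nulls preserve the size profile", {
  genes <- sprintf("g%d", 1:24)
  ann <- annotation_map(setNames(as.list(rep(paste0("P", 1:4), each = 6)),
                                 genes))
  units <- list(c1 = genes[1:6], c2 = genes[7:18], c3 = genes[19:24])
  ns <- null_homogeneity(units, "shuffle_clusters", ann,
                         n_resamples = 30, seed = 2)
  expect_equal(sum(ns$per_bin$n_units), 3L)
  # c1 and c3 are pathway-pure (bin 6-10 mean 1); c2 straddles two
  # pathways (homogeneity 1/2); shuffling degrades the pure bins
  expect_equal(ns$per_bin$real_mean[ns$per_bin$label == "6-10"], 1)
  expect_equal(ns$per_bin$real_mean[ns$per_bin$label == "11-15"], 0.5)
  expect_true(all(ns$per_bin$null_mean < 1))
})

test_that("HINscore nulls hit their extremes on complete and empty graphs", {
  genes <- sprintf("g%d", 1:10)
  pairs <- t(combn(genes, 2))
  full <- hin_network(data.frame(a = pairs[, 1], b = pairs[, 2]))
  units <- list(u1 = genes[1:4], u2 = genes[3:8])
  ns <- null_hinscore(units, full, pool = genes, n_resamples = 25, seed = 3)
  expect_true(all(ns$per_bin$null_mean == 1))
  expect_true(all(ns$per_bin$real_mean == 1))
  empty <- hin_network(data.frame(a = character(0), b = character(0)),
                       nodes = genes)
  ns0 <- null_hinscore(units, empty, pool = genes, n_resamples = 25,
                       seed = 3)
  expect_true(all(ns0$per_bin$null_mean == 0))
  expect_error(null_hinscore(list(u = sprintf("g%d", 1:11)), full,
                             pool = genes, n_resamples = 5),
               class = "dgnet_input_error")
})
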