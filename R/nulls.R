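# Resampling null models and binned summaries.
#
# Real statistics (homogeneity, HINscore) are compared per size-bin against
# size-matched random controls: for each resample a random counterpart of
# every unit is drawn and the statistic recomputed; the per-bin means of
# these resampled statistics form the null distribution of the bin mean.
# Empirical p-values use the +1/(N+1) correction so they are never 0.

#' Default size bins
#'
#' Disjoint intervals covering unit sizes from 2 upward: 2-5, 6-10, 11-15,
#' 16-30, 31-50, 51-100, >100.
#'
#' @return data.frame with `lo`, `hi`, `label`.
#' @export
default_bins <- function() {
  data.frame(lo = c(2, 6, 11, 16, 31, 51, 101),
             hi = c(5, 10, 15, 30, 50, 100, Inf),
             label = c("2-5", "6-10", "11-15", "16-30", "31-50",
                       "51-100", ">100"),
             stringsAsFactors = FALSE)
}

validate_bins <- function(bins) {
  if (!all(c("lo", "hi") %in% names(bins)))
    stop_config("bins need 'lo' and 'hi' columns")
  o <- order(bins$lo)
  bins <- bins[o, , drop = FALSE]
  if (any(bins$hi < bins$lo)) stop_config("bin with hi < lo")
  if (nrow(bins) > 1L &&
      any(bins$lo[-1L] <= bins$hi[-nrow(bins)]))
    stop_config("overlapping size bins")
  if (is.null(bins$label))
    bins$label <- ifelse(is.finite(bins$hi),
                         paste0(bins$lo, "-", bins$hi),
                         paste0(">", bins$lo - 1))
  bins
}

assign_bins <- function(sizes, bins) {
  out <- rep(NA_integer_, length(sizes))
  for (i in seq_len(nrow(bins)))
    out[sizes >= bins$lo[i] & sizes <= bins$hi[i]] <- i
  out
}

#' Binned means with 95% confidence intervals
#'
#' Groups unit-level statistics by size bin and reports per-bin mean with a
#' t-based 95% CI across units; bins holding fewer than 2 units report the
#' mean without a CI, and empty bins are absent from the output.
#'
#' @param sizes Integer unit sizes.
#' @param values Statistic values (same length).
#' @param bins Bin table as from [default_bins()]; must be disjoint.
#' @return data.frame `label`, `lo`, `hi`, `n`, `mean`, `ci_lo`, `ci_hi`.
#' @export
bin_by_size <- function(sizes, values, bins = default_bins()) {
  if (length(sizes) != length(values))
    stop_input("sizes and values differ in length")
  bins <- validate_bins(bins)
  ok <- is.finite(values)
  b <- assign_bins(sizes[ok], bins)
  v <- values[ok]
  rows <- lapply(sort(unique(b[!is.na(b)])), function(i) {
    x <- v[!is.na(b) & b == i]
    n <- length(x)
    m <- mean(x)
    if (n >= 2L && stats::sd(x) > 0) {
      half <- stats::qt(0.975, n - 1L) * stats::sd(x) / sqrt(n)
      ci <- c(m - half, m + half)
    } else if (n >= 2L) {
      ci <- c(m, m)
    } else {
      ci <- c(NA_real_, NA_real_)
    }
    data.frame(label = bins$label[i], lo = bins$lo[i], hi = bins$hi[i],
               n = n, mean = m, ci_lo = ci[1L], ci_hi = ci[2L],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(label = character(0), lo = numeric(0),
                      hi = numeric(0), n = integer(0), mean = numeric(0),
                      ci_lo = numeric(0), ci_hi = numeric(0),
                      stringsAsFactors = FALSE)
  out
}

new_null_summary <- function(statistic_name, n_resamples, per_bin,
                             pearson_r, seed) {
  structure(list(statistic_name = statistic_name,
                 n_resamples = n_resamples, per_bin = per_bin,
                 pearson_r = pearson_r, seed = seed),
            class = "dgnet_null_summary")
}

#' @export
print.dgnet_null_summary <- function(x, ...) {
  cat(sprintf("%s null summary (%d resamples, seed %d)\n",
              x$statistic_name, x$n_resamples, x$seed))
  print(x$per_bin)
  invisible(x)
}

# shared machinery: real per-unit (size, value), a sampler producing one
# resampled value per unit, bin bookkeeping and empirical p-values
null_summary_engine <- function(statistic_name, sizes, values,
                                resample_values, n_resamples, seed, bins,
                                pearson_r) {
  bins <- validate_bins(bins)
  ok <- is.finite(values)
  sizes <- sizes[ok]; values <- values[ok]
  bin_of <- assign_bins(sizes, bins)
  used <- sort(unique(bin_of[!is.na(bin_of)]))
  if (!length(used))
    return(new_null_summary(statistic_name, n_resamples,
                            bin_by_size(numeric(0), numeric(0), bins),
                            pearson_r, seed))
  in_bin <- !is.na(bin_of)
  grp <- factor(bin_of[in_bin], levels = used)
  real_bm <- tapply(values[in_bin], grp, mean)
  null_bm <- matrix(NA_real_, n_resamples, length(used))
  for (r in seq_len(n_resamples)) {
    vr <- resample_values(ok)
    vr <- vr[in_bin]
    null_bm[r, ] <- tapply(vr, grp, mean, na.rm = TRUE)
  }
  real_tab <- bin_by_size(sizes, values, bins)
  per_bin <- data.frame(
    label = bins$label[used], lo = bins$lo[used], hi = bins$hi[used],
    n_units = as.integer(table(grp)),
    real_mean = as.numeric(real_bm),
    real_ci_lo = real_tab$ci_lo[match(bins$label[used], real_tab$label)],
    real_ci_hi = real_tab$ci_hi[match(bins$label[used], real_tab$label)],
    null_mean = colMeans(null_bm, na.rm = TRUE),
    null_ci_lo = apply(null_bm, 2L, stats::quantile, probs = 0.025,
                       na.rm = TRUE, names = FALSE),
    null_ci_hi = apply(null_bm, 2L, stats::quantile, probs = 0.975,
                       na.rm = TRUE, names = FALSE),
    stringsAsFactors = FALSE)
  per_bin$p_empirical <- vapply(seq_along(used), function(j) {
    nb <- null_bm[, j]
    nb <- nb[is.finite(nb)]
    (1 + sum(nb >= real_bm[j])) / (1 + length(nb))
  }, numeric(1))
  rownames(per_bin) <- NULL
  new_null_summary(statistic_name, n_resamples, per_bin, pearson_r, seed)
}

#' Resampling null model for pathway homogeneity
#'
#' Two randomization schemes: `"sample_genes"` draws, for each unit, the
#' same number of genes as the unit's annotated genes from the pool of
#' pathway-annotated disease genes of the studied network (without
#' replacement) and recomputes homogeneity — the control for single
#' diseases and disease clusters. `"shuffle_clusters"` permutes the
#' multiset of clustered genes over the fixed cluster-size profile — the
#' control for gene clusters. Per size bin the real mean is compared with
#' the distribution of resampled bin means: percentile 95% null CIs and the
#' empirical p-value `(1 + #[null >= real]) / (1 + N)`. Significance is
#' conventionally read at 0.05.
#'
#' @param units Named list of gene-id vectors.
#' @param mode `"sample_genes"` or `"shuffle_clusters"`.
#' @param ann A `dgnet_annotation`.
#' @param pool Sampling pool of gene ids (`sample_genes` mode); restricted
#'   to annotated genes. Ignored in `shuffle_clusters` mode, where the
#'   pool is the multiset of clustered genes itself.
#' @param n_resamples Number of resamples (default `1e4`).
#' @param seed Integer seed driving all resampling.
#' @param bins Size bins; `sample_genes` units are binned by annotated
#'   gene count, `shuffle_clusters` units by total cluster size.
#' @return A `dgnet_null_summary`: per-bin real/null means, CIs and
#'   empirical p, plus the Pearson correlation between homogeneity and
#'   unit size over real units.
#' @export
null_homogeneity <- function(units, mode = c("sample_genes",
                                             "shuffle_clusters"),
                             ann, pool = NULL, n_resamples = 10000L,
                             seed = 1L, bins = default_bins()) {
  mode <- match.arg(mode)
  if (!is.numeric(n_resamples) || n_resamples < 1)
    stop_config("n_resamples must be a positive integer")
  n_resamples <- as.integer(n_resamples)
  stopifnot(inherits(ann, "dgnet_annotation"))
  real <- homogeneity_table(units, ann)
  pr <- homogeneity_size_correlation(real)
  if (mode == "sample_genes") {
    pool <- pool %||% annotated_genes(ann)
    pool <- intersect(unique(pool), annotated_genes(ann))
    if (!length(pool)) stop_config("empty annotated sampling pool")
    enc <- encode_annotation(ann, pool)
    sizes <- real$n_annotated
    too_big <- real$n_annotated > length(pool)
    if (any(too_big))
      stop_input("unit '%s' larger than the sampling pool (%d > %d)",
                 real$unit_id[which(too_big)[1L]],
                 real$n_annotated[which(too_big)[1L]], length(pool))
    npool <- length(pool)
    draw_sizes <- real$n_annotated
    resample_values <- function(ok) {
      vapply(seq_len(nrow(real)), function(u) {
        s <- draw_sizes[u]
        if (s == 0L) return(NA_real_)
        homog_fast(sample.int(npool, s), enc)
      }, numeric(1))[ok]
    }
  } else {
    all_genes <- unlist(units, use.names = FALSE)
    if (!length(all_genes)) stop_config("no clustered genes to shuffle")
    enc <- encode_annotation(ann, all_genes)
    sizes <- real$n_total
    csizes <- lengths(units)
    ends <- cumsum(csizes)
    starts <- ends - csizes + 1L
    ntot <- length(all_genes)
    resample_values <- function(ok) {
      perm <- sample.int(ntot)
      vapply(seq_along(csizes), function(u)
        homog_fast(perm[starts[u]:ends[u]], enc), numeric(1))[ok]
    }
  }
  with_seed(seed,
    null_summary_engine("pathway_homogeneity", sizes, real$value,
                        resample_values, n_resamples, seed, bins, pr$r))
}

#' Resampling null model for the HINscore
#'
#' For each real cluster and each resample, a size-matched gene set is
#' drawn without replacement from the pool of network genes present in the
#' interaction network, and its HINscore computed. Per-bin summaries and
#' empirical p-values as in [null_homogeneity()]; units are binned by
#' total gene count, and units with fewer than 2 genes (undefined score)
#' are dropped.
#'
#' @param units Named list of gene-id vectors (typically gene clusters).
#' @param hin A `dgnet_hin` network.
#' @param pool Sampling pool; intersected with `hin` nodes. Defaults to
#'   all `hin` nodes.
#' @param n_resamples,seed,bins As in [null_homogeneity()].
#' @return A `dgnet_null_summary`.
#' @export
null_hinscore <- function(units, hin, pool = NULL, n_resamples = 10000L,
                          seed = 1L, bins = default_bins()) {
  if (!is.numeric(n_resamples) || n_resamples < 1)
    stop_config("n_resamples must be a positive integer")
  n_resamples <- as.integer(n_resamples)
  stopifnot(inherits(hin, "dgnet_hin"))
  pool <- intersect(unique(pool %||% hin$nodes), hin$nodes)
  if (!length(pool)) stop_config("empty HIN sampling pool")
  sizes <- vapply(units, function(g) length(unique(g)), integer(1))
  if (any(sizes > length(pool)))
    stop_input("unit '%s' larger than the HIN sampling pool",
               names(units)[which(sizes > length(pool))[1L]])
  real_values <- vapply(units, hin_score, numeric(1), hin = hin)
  real <- data.frame(value = real_values, n_annotated = sizes)
  pr <- homogeneity_size_correlation(real)
  idx <- hin_index(hin, pool)
  npool <- length(pool)
  score_idx <- function(unit_idx) {
    n <- length(unit_idx)
    if (n < 2L) return(NA_real_)
    (n - count_components_idx(unit_idx, idx)) / (n - 1)
  }
  resample_values <- function(ok) {
    vapply(sizes, function(s) {
      if (s < 2L) return(NA_real_)
      score_idx(sample.int(npool, s))
    }, numeric(1))[ok]
  }
  with_seed(seed,
    null_summary_engine("hin_score", sizes, real_values, resample_values,
                        n_resamples, seed, bins, pr$r))
}
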