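# End-to-end pipeline: read -> filter -> build -> simplify -> project ->
# cluster -> homogeneity/HINscore with nulls -> enrichment -> report.
# Configuration comes from run_config() or a YAML file; every output file
# carries the tool version, a config hash and the seed, and a DONE
# sentinel marks a complete run.

#' Pipeline configuration
#'
#' Validates input paths at construction time (a missing path is a
#' configuration error raised before any computation starts).
#'
#' @param associations Path to the association TSV.
#' @param annotation Path to a GMT or two-column `gene_id  term_id` TSV.
#' @param hin Optional path to the interaction-network edge list / SIF.
#' @param network Source preset (`"OMIM"`, `"CURATED"`, `"LHGDN"`,
#'   `"ALL"`) or explicit source vector.
#' @param side Projection side to cluster (`"disease"` or `"gene"`).
#' @param mcl [mcl_params()].
#' @param bins Size-bin table, default [default_bins()].
#' @param n_resamples Resamples for the null models.
#' @param seed Integer seed for all resampling.
#' @param out_dir Output directory (created if absent).
#' @return List of class `dgnet_run_config`.
#' @export
run_config <- function(associations, annotation, hin = NULL,
                       network = "ALL", side = c("disease", "gene"),
                       mcl = mcl_params(), bins = default_bins(),
                       n_resamples = 10000L, seed = 1L,
                       out_dir = "dgnet_out") {
  side <- match.arg(side)
  for (p in c(associations, annotation, hin))
    if (!file.exists(p)) stop_config("input path does not exist: %s", p)
  if (!is.numeric(n_resamples) || n_resamples < 1)
    stop_config("n_resamples must be a positive integer")
  structure(list(associations = associations, annotation = annotation,
                 hin = hin, network = network, side = side, mcl = mcl,
                 bins = validate_bins(bins),
                 n_resamples = as.integer(n_resamples),
                 seed = as.integer(seed), out_dir = out_dir),
            class = "dgnet_run_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Recognized keys mirror the [run_config()] arguments; `mcl` may be a
#' mapping of [mcl_params()] fields. Entries in `overrides` take
#' precedence over the file, which takes precedence over the defaults.
#'
#' @param path YAML file path.
#' @param overrides Named list of values overriding the file.
#' @return A `dgnet_run_config`.
#' @export
read_run_config <- function(path, overrides = list()) {
  if (!file.exists(path)) stop_config("config file not found: %s", path)
  y <- yaml::read_yaml(path)
  y[names(overrides)] <- overrides
  if (!is.null(y$mcl)) y$mcl <- do.call(mcl_params, y$mcl)
  if (!is.null(y$bins)) y$bins <- as.data.frame(y$bins)
  args <- y[intersect(names(y), names(formals(run_config)))]
  do.call(run_config, args)
}

pipeline_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    if (inherits(e, "dgnet_stage_error")) stop(e)
    stop_stage(stage, e)
  })
}

#' Run the full gene-disease modularity pipeline
#'
#' Executes read, ontology filtering, bipartite construction,
#' simplification, projection with overlap weights, MCL clustering,
#' pathway-homogeneity and HINscore statistics with their resampling
#' nulls, and enrichment, writing all artifacts to `config$out_dir`:
#' `network_bipartite.tsv`/`.sif`, `network_projection.tsv`,
#' `clusters.tsv` + `clusters_meta.json`, `units_stats.tsv`,
#' `bins_stats.tsv`, `enrichment.tsv`, `summary.json`, and a `DONE`
#' sentinel on success. Timing and stage progress are logged to stderr.
#'
#' @param config A `dgnet_run_config`.
#' @return Invisibly, a list with the main in-memory results (`network`,
#'   `projection`, `clustering`, `homogeneity`, `null_homogeneity`,
#'   `hin_null`, `enrichment`, `summary`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "dgnet_run_config"))
  t0 <- Sys.time()
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  done <- file.path(config$out_dir, "DONE")
  if (file.exists(done)) unlink(done)
  # hash over the result-determining fields only (not the output location)
  hash <- config_hash(unclass(config)[setdiff(names(config), "out_dir")])
  log_msg <- function(fmt, ...)
    message(sprintf("[dgnet %s] %s", format(Sys.time(), "%H:%M:%S"),
                    sprintf(fmt, ...)))

  log_msg("reading associations from %s", config$associations)
  records <- pipeline_stage("read_associations",
                            read_associations(config$associations))
  ann <- pipeline_stage("read_annotation", {
    first <- readLines(config$annotation, n = 5L, warn = FALSE)
    first <- first[!startsWith(first, "#") & nzchar(first)]
    if (length(first) && grepl("^gene_id\tterm_id", first[1L]))
      read_annotation_tsv(config$annotation)
    else read_gmt(config$annotation)
  })
  hin <- if (!is.null(config$hin))
    pipeline_stage("read_hin", read_hin(config$hin)) else NULL

  log_msg("building %s network", paste(config$network, collapse = "+"))
  net <- pipeline_stage("build_bipartite", {
    simplify_bipartite(build_bipartite(filter_for_analysis(records),
                                       config$network))
  })
  write_edgelist(net, file.path(config$out_dir, "network_bipartite.tsv"),
                 seed = config$seed, hash = hash)
  write_sif(net, file.path(config$out_dir, "network_bipartite.sif"))

  log_msg("projecting to the %s side", config$side)
  proj <- pipeline_stage("project", project(net, config$side))
  write_edgelist(proj, file.path(config$out_dir, "network_projection.tsv"),
                 seed = config$seed, hash = hash)

  log_msg("MCL clustering (%d nodes)", length(proj$nodes))
  clustering <- pipeline_stage("mcl", mcl(proj, config$mcl))
  write_clusters(clustering, file.path(config$out_dir, "clusters.tsv"),
                 seed = config$seed, hash = hash)
  write_cluster_meta(clustering,
                     file.path(config$out_dir, "clusters_meta.json"),
                     seed = config$seed)

  log_msg("homogeneity statistics and null model (%d resamples)",
          config$n_resamples)
  units <- pipeline_stage("units", {
    if (config$side == "disease")
      cluster_units(clustering, net, "disease")
    else cluster_units(clustering, side = "gene")
  })
  dunits <- disease_units(net)
  hom <- pipeline_stage("homogeneity", homogeneity_table(units, ann))
  dis_hom <- homogeneity_table(dunits, ann)
  pool <- intersect(net$genes, annotated_genes(ann))
  null_mode <- if (config$side == "gene") "shuffle_clusters"
               else "sample_genes"
  nh <- pipeline_stage("null_homogeneity",
    null_homogeneity(units, null_mode, ann, pool = pool,
                     n_resamples = config$n_resamples,
                     seed = config$seed, bins = config$bins))
  hin_null <- NULL
  hin_scores <- rep(NA_real_, length(units))
  if (!is.null(hin)) {
    log_msg("HINscore statistics and null model")
    hin_scores <- vapply(units, hin_score, numeric(1), hin = hin)
    hpool <- intersect(net$genes, hin$nodes)
    big <- lengths(units) > length(hpool)
    hin_null <- pipeline_stage("null_hinscore",
      null_hinscore(units[!big], hin, pool = hpool,
                    n_resamples = config$n_resamples,
                    seed = config$seed, bins = config$bins))
  }

  unit_stats <- data.frame(
    unit_id = hom$unit_id, n_total = hom$n_total,
    n_annotated = hom$n_annotated, homogeneity = hom$value,
    top_term = hom$top_term, hin_score = unname(hin_scores),
    stringsAsFactors = FALSE)
  write_tsv_with_header(unit_stats,
                        file.path(config$out_dir, "units_stats.tsv"),
                        seed = config$seed, hash = hash)
  bin_out <- nh$per_bin
  bin_out$statistic <- "pathway_homogeneity"
  if (!is.null(hin_null)) {
    hb <- hin_null$per_bin
    hb$statistic <- "hin_score"
    bin_out <- rbind(bin_out, hb)
  }
  write_tsv_with_header(bin_out,
                        file.path(config$out_dir, "bins_stats.tsv"),
                        seed = config$seed, hash = hash)

  log_msg("enrichment over %d cluster units", length(units))
  enr <- pipeline_stage("enrichment", enrich_units(units, ann, pool))
  write_tsv_with_header(enr, file.path(config$out_dir, "enrichment.tsv"),
                        seed = config$seed, hash = hash)

  summary <- list(
    version = pkg_version(), seed = config$seed, config_hash = hash,
    network = paste(config$network, collapse = "+"), side = config$side,
    n_genes = length(net$genes), n_diseases = length(net$diseases),
    n_edges = nrow(net$edges),
    mean_degree_gene = degree_summary(net, "gene")$mean_degree,
    mean_degree_disease = degree_summary(net, "disease")$mean_degree,
    n_clusters = length(clustering$clusters),
    n_unclustered = length(clustering$unclustered),
    mcl_converged = clustering$converged,
    mean_disease_homogeneity = mean(dis_hom$value, na.rm = TRUE),
    homogeneity_size_r = nh$pearson_r,
    n_significant_terms = sum(enr$p_value < 0.05),
    elapsed_sec = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  writeLines(format(Sys.time()), done)
  log_msg("done in %.1fs", summary$elapsed_sec)
  invisible(list(network = net, projection = proj,
                 clustering = clustering, homogeneity = hom,
                 null_homogeneity = nh, hin_null = hin_null,
                 enrichment = enr, summary = summary))
}
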