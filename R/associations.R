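# Association records and the gene-disease association ontology.
#
# A record set is a data.frame with columns
#   gene_id, disease_id, source, original_label, assoc_type, certainty, evidence
# where `evidence` is a list column of character vectors (literature ids) and
# assoc_type is NA exactly when certainty == "NoAssociation".

ASSOC_SOURCES <- c("OMIM", "UNIPROT", "PHARMGKB", "CTD", "LHGDN", "SYNTH")
ASSOC_TYPES   <- c("Marker", "GeneticVariation", "RegulatoryModification",
                   "Therapeutic")
CERTAINTY     <- c("Association", "NoAssociation")

#' Built-in source-label vocabulary of the association ontology
#'
#' Maps each source database's original association label to an ontology
#' class (`Marker`, `GeneticVariation`, `RegulatoryModification`,
#' `Therapeutic`) and a certainty class (`Association` / `NoAssociation`).
#' OMIM `"phenotype"` entries are Marker associations; UniProt variant
#' annotations are GeneticVariation; PharmGKB `"Related"` is Marker while
#' `"Positively Related"` / `"Negatively Related"` are
#' RegulatoryModification and `"not related"` is NoAssociation; CTD
#' `"marker"` / `"therapeutic"` map to the classes of the same name; LHGDN
#' `"negative association"` is NoAssociation.
#'
#' In addition to these nine entries, an `original_label` equal to an
#' ontology class name resolves to that class as an Association for any
#' source; synthetic exports use this pass-through.
#'
#' @return A data.frame of class `dgnet_label_map` with columns `source`,
#'   `original_label`, `assoc_type`, `certainty`.
#' @examples
#' m <- default_label_map()
#' subset(m, source == "CTD")
#' @export
default_label_map <- function() {
  m <- data.frame(
    source = c("OMIM", "UNIPROT", "PHARMGKB", "PHARMGKB", "PHARMGKB",
               "PHARMGKB", "CTD", "CTD", "LHGDN"),
    original_label = c("phenotype", "disease_variant", "Related",
                       "Positively Related", "Negatively Related",
                       "not related", "marker", "therapeutic",
                       "negative association"),
    assoc_type = c("Marker", "GeneticVariation", "Marker",
                   "RegulatoryModification", "RegulatoryModification",
                   NA, "Marker", "Therapeutic", NA),
    certainty = c("Association", "Association", "Association",
                  "Association", "Association", "NoAssociation",
                  "Association", "Association", "NoAssociation"),
    stringsAsFactors = FALSE)
  class(m) <- c("dgnet_label_map", "data.frame")
  m
}

# resolve (source, label) pairs through a label map; `line` used in errors
resolve_labels <- function(source, original_label, label_map, line = NULL) {
  key <- paste(source, original_label, sep = "\r")
  mkey <- paste(label_map$source, label_map$original_label, sep = "\r")
  idx <- match(key, mkey)
  assoc_type <- label_map$assoc_type[idx]
  certainty <- label_map$certainty[idx]
  # pass-through: labels that are themselves ontology class names
  pass <- is.na(idx) & original_label %in% ASSOC_TYPES
  assoc_type[pass] <- original_label[pass]
  certainty[pass] <- "Association"
  bad <- is.na(idx) & !pass
  if (any(bad)) {
    i <- which(bad)[1L]
    where <- if (is.null(line)) "" else sprintf(" (line %d)", line[i])
    stop_format("unknown (source, original_label) pair: (%s, %s)%s",
                source[i], original_label[i], where)
  }
  list(assoc_type = assoc_type, certainty = certainty)
}

new_associations <- function(df) {
  df <- df[order(df$gene_id, df$disease_id, df$source, df$original_label), ,
           drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("dgnet_associations", "data.frame")
  df
}

# collapse duplicate (gene, disease, source, label) rows; evidence is unioned
collapse_duplicates <- function(df) {
  key <- paste(df$gene_id, df$disease_id, df$source, df$original_label,
               sep = "\r")
  if (!anyDuplicated(key)) return(df)
  ev <- lapply(split(df$evidence, key), function(e) sort(unique(unlist(e))))
  first <- !duplicated(key)
  out <- df[first, , drop = FALSE]
  out$evidence <- unname(ev[paste(out$gene_id, out$disease_id, out$source,
                                  out$original_label, sep = "\r")])
  out
}

#' Read gene-disease association records from a TSV file
#'
#' The file must be tab-separated with header columns `gene_id`,
#' `disease_id`, `source`, `original_label`, `evidence` (pipe-separated
#' literature ids, possibly empty). Lines starting with `#` are ignored.
#' Each `(source, original_label)` pair is resolved through `label_map`;
#' an unknown pair is a format error naming the pair and line number.
#' Duplicate rows collapse to a single record whose evidence is the union.
#'
#' @param path Path to the TSV file.
#' @param label_map A label map, by default [default_label_map()].
#' @return A `dgnet_associations` data.frame.
#' @seealso [write_associations()], [filter_for_analysis()]
#' @export
read_associations <- function(path, label_map = default_label_map()) {
  if (!file.exists(path)) stop_config("association file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !startsWith(lines, "#") & nzchar(lines)
  lineno <- which(keep)
  if (!length(lineno)) stop_format("empty association file: %s", path)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  header <- fields[[1L]]
  required <- c("gene_id", "disease_id", "source", "original_label",
                "evidence")
  missing <- setdiff(required, header)
  if (length(missing))
    stop_format("association file %s is missing column '%s'", path,
                missing[1L])
  col <- match(required, header)
  rows <- fields[-1L]
  lineno <- lineno[-1L]
  get <- function(j) vapply(rows, function(r) {
    if (length(r) >= col[j]) r[col[j]] else ""
  }, character(1))
  gene_id <- get(1L); disease_id <- get(2L)
  source <- get(3L); original_label <- get(4L); evidence <- get(5L)
  if (any(!nzchar(gene_id)) || any(!nzchar(disease_id))) {
    i <- which(!nzchar(gene_id) | !nzchar(disease_id))[1L]
    stop_format("empty gene_id or disease_id at line %d", lineno[i])
  }
  bad_src <- !(source %in% ASSOC_SOURCES)
  if (any(bad_src)) {
    i <- which(bad_src)[1L]
    stop_format("unknown source '%s' at line %d", source[i], lineno[i])
  }
  res <- resolve_labels(source, original_label, label_map, lineno)
  df <- data.frame(gene_id = gene_id, disease_id = disease_id,
                   source = source, original_label = original_label,
                   assoc_type = res$assoc_type, certainty = res$certainty,
                   stringsAsFactors = FALSE)
  df$evidence <- lapply(strsplit(evidence, "|", fixed = TRUE),
                        function(e) sort(unique(e[nzchar(e)])))
  new_associations(collapse_duplicates(df))
}

#' Write association records to TSV
#'
#' Inverse of [read_associations()]: `read_associations(write_associations(x))`
#' is the identity on canonicalized record sets.
#'
#' @param records A `dgnet_associations` data.frame.
#' @param path Output path.
#' @param seed Optional seed recorded in the file header comment.
#' @return The path, invisibly.
#' @export
write_associations <- function(records, path, seed = NULL) {
  out <- data.frame(
    gene_id = records$gene_id, disease_id = records$disease_id,
    source = records$source, original_label = records$original_label,
    evidence = vapply(records$evidence, paste, character(1), collapse = "|"),
    stringsAsFactors = FALSE)
  write_tsv_with_header(out, path, seed = seed)
}

#' Keep only records with certainty class Association
#'
#' The analysis networks are built only from positive associations;
#' NoAssociation records (explicit evidence of independence between a gene
#' and a disease state) round-trip through I/O but never enter a network.
#' Idempotent; the input is not modified.
#'
#' @param records A `dgnet_associations` data.frame.
#' @return The subset with `certainty == "Association"`.
#' @export
filter_for_analysis <- function(records) {
  out <- records[records$certainty == "Association", , drop = FALSE]
  rownames(out) <- NULL
  out
}
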