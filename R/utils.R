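# shared internal helpers: error classes, seeds, output headers

`%||%` <- function(a, b) if (is.null(a)) b else a

pkg_version <- function() as.character(utils::packageVersion("dgnet"))

# deterministic child seeds; kept < 2^31 so they are valid R integer seeds
derive_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 69069 + as.numeric(i) * 1664525 + 1013904223) %%
               2147483647)
}

stop_config <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("dgnet_config_error", "dgnet_error", "error")))
}

stop_format <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("dgnet_format_error", "dgnet_error", "error")))
}

stop_input <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("dgnet_input_error", "dgnet_error", "error")))
}

stop_stage <- function(stage, parent) {
  stop(errorCondition(
    sprintf("stage '%s' failed: %s", stage, conditionMessage(parent)),
    class = c("dgnet_stage_error", "dgnet_error", "error")))
}

config_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(paste(deparse(x), collapse = "\n"), f)
  unname(tools::md5sum(f))
}

output_header <- function(seed = NULL, hash = NULL) {
  h <- sprintf("# dgnet %s", pkg_version())
  if (!is.null(seed)) h <- c(h, sprintf("# seed: %s", format(seed)))
  if (!is.null(hash)) h <- c(h, sprintf("# config_hash: %s", hash))
  h
}

write_tsv_with_header <- function(df, path, seed = NULL, hash = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(output_header(seed, hash), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv_skip_comments <- function(path, ...) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE, ...)
}

# run expr with a locally seeded RNG, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
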