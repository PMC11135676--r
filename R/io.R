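## Canonical table dialect: tab-delimited, header row, UTF-8, "." decimal,
## "#"-prefixed provenance comment lines before the header.

pk_version <- function() {
  as.character(utils::packageVersion("pulchkin"))
}

## Cheap deterministic hex digest of a config (FNV-1a over the YAML text).
## Paths are excluded so the digest identifies the parameters, not where
## the run happened to write.
config_hash <- function(config) {
  config$outdir <- NULL
  bytes <- utf8ToInt(yaml::as.yaml(config))
  h <- 2166136261
  for (b in bytes) h <- (bitwXor(as.integer(h %% 2^31), b) * 16777619) %% 2^31
  sprintf("%08x", as.integer(h))
}

#' Write a TSV table with provenance header comments
#'
#' @param df data.frame.
#' @param path output file.
#' @param meta named character vector written as `# key: value` lines.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(df, path, meta = character(0)) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("# pulchkin %s", pk_version()), con)
  for (k in names(meta)) writeLines(sprintf("# %s: %s", k, meta[[k]]), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "")
  invisible(path)
}

#' Read a TSV table written by this package
#'
#' @param path input file.
#' @param required_cols columns that must be present; a missing column
#'   raises a schema error naming it.
#' @return data.frame.
#' @export
read_tsv <- function(path, required_cols = NULL) {
  pk_assert(file.exists(path), sprintf("file not found: %s", path),
            class = "io_error")
  df <- utils::read.delim(path, comment.char = "#", sep = "\t",
                          stringsAsFactors = FALSE)
  missing <- setdiff(required_cols, names(df))
  if (length(missing) > 0)
    pk_stop(sprintf("%s: missing column(s) %s", path,
                    paste(missing, collapse = ", ")), "schema_error")
  df
}
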