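# Shared helpers: chromosome-label normalization and strict TSV IO.

#' Normalize chromosome labels to the chr-prefixed form
#'
#' Catalog files often label chromosomes "1", "X" while interval files use
#' "chr1", "chrX"; all labels are normalized at parse time so the two
#' conventions join correctly.
#'
#' @param x Character vector of chromosome labels.
#' @return Character vector with a `chr` prefix on every label.
#' @export
normalize_chrom <- function(x) {
  x <- as.character(x)
  ifelse(grepl("^chr", x), x, paste0("chr", x))
}

# Read a TSV with a fixed header, failing loudly when columns are missing.
read_strict_tsv <- function(path, required, what = "table") {
  if (!file.exists(path)) {
    stop(sprintf("%s file not found: %s", what, path), call. = FALSE)
  }
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character",
                          check.names = FALSE, quote = "",
                          comment.char = "")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop(sprintf("%s file %s is missing column(s): %s",
                 what, path, paste(missing, collapse = ", ")),
         call. = FALSE)
  }
  df
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

# Parse a numeric column, reporting 1-based data-row numbers of failures.
parse_numeric_column <- function(x, column, path) {
  out <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(out) & !is.na(x))
  if (length(bad) > 0) {
    stop(sprintf("malformed %s at data row(s) %s of %s",
                 column, paste(bad, collapse = ", "), path),
         call. = FALSE)
  }
  out
}
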