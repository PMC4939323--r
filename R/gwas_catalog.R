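# GWAS catalog stage: parse lead-SNP association records and filter them by
# association p-value and study population.

#' Load a GWAS lead-SNP catalog
#'
#' Reads a tab-separated catalog of lead associations with columns
#' `snp_id`, `p_value`, `chrom`, `population`, `pmid`. P-values in
#' scientific notation are parsed; chromosome labels are normalized to the
#' `chr`-prefixed form; row order is preserved.
#'
#' @param path Path to the catalog TSV.
#' @return A data.frame of lead records, one per data row.
#' @export
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' write_catalog(make_gwas_fixture(), f)
#' nrow(load_catalog(f))  # 45
load_catalog <- function(path) {
  df <- read_strict_tsv(path, c("snp_id", "p_value", "chrom",
                                "population", "pmid"), "catalog")
  df <- df[, c("snp_id", "p_value", "chrom", "population", "pmid")]
  df$p_value <- parse_numeric_column(df$p_value, "p_value", path)
  bad_p <- which(!(df$p_value > 0 & df$p_value <= 1))
  if (length(bad_p) > 0) {
    stop(sprintf("p_value outside (0, 1] at data row(s) %s of %s",
                 paste(bad_p, collapse = ", "), path), call. = FALSE)
  }
  if (any(!nzchar(df$snp_id))) {
    stop("empty snp_id in catalog ", path, call. = FALSE)
  }
  # a SNP may recur under different populations; the (snp_id, population)
  # pair must be unique
  key <- paste(df$snp_id, df$population)
  if (anyDuplicated(key)) {
    stop(sprintf("duplicate snp_id within a population in %s: %s", path,
                 paste(unique(df$snp_id[duplicated(key)]), collapse = ", ")),
         call. = FALSE)
  }
  df$chrom <- normalize_chrom(df$chrom)
  rownames(df) <- NULL
  df
}

#' Write a GWAS catalog to TSV
#'
#' Inverse of [load_catalog()]: `load_catalog(write_catalog(x, f))`
#' reproduces `x` field for field.
#'
#' @param catalog Catalog data.frame as returned by [load_catalog()].
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_catalog <- function(catalog, path) {
  out <- catalog
  out$p_value <- format(out$p_value, scientific = TRUE, digits = 15)
  write_tsv(out, path)
}

#' Filter lead SNPs by p-value and population
#'
#' Keeps records with `p_value` strictly below `p_threshold` and, when
#' `populations` is given, population in that set. Order is preserved and
#' the operation is idempotent.
#'
#' @param catalog Catalog data.frame.
#' @param p_threshold Keep records with p-value strictly below this
#'   (default `1e-5`, the conventional genome-wide suggestive threshold
#'   used by the packaged catalog).
#' @param populations Optional character vector of cohort codes; `NULL`
#'   keeps all populations. An empty vector is rejected as ambiguous.
#' @return The filtered catalog data.frame.
#' @export
#' @examples
#' cat45 <- make_gwas_fixture()
#' nrow(filter_leads(cat45, 1e-5))                        # 45
#' nrow(filter_leads(cat45, 1e-5, populations = "CHB"))   # 26
filter_leads <- function(catalog, p_threshold = 1e-5, populations = NULL) {
  stopifnot(is.numeric(p_threshold), length(p_threshold) == 1,
            p_threshold > 0, p_threshold <= 1)
  if (!is.null(populations) && length(populations) == 0) {
    stop("populations must be NULL or a non-empty set of cohort codes",
         call. = FALSE)
  }
  keep <- catalog$p_value < p_threshold
  if (!is.null(populations)) {
    keep <- keep & catalog$population %in% populations
  }
  out <- catalog[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
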