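# Validation of enhancer SNPs against a regulatory-variant annotation
# table (rVarBase-style): per-SNP regulatory and distal-regulation flags,
# chromatin states, related elements, and distal target-gene links.

parse_flag <- function(x, column, path) {
  v <- tolower(trimws(x))
  out <- v %in% c("yes", "true", "1")
  bad <- which(!(v %in% c("yes", "no", "true", "false", "1", "0")))
  if (length(bad) > 0) {
    stop(sprintf("unrecognized %s flag at data row(s) %s of %s",
                 column, paste(bad, collapse = ", "), path), call. = FALSE)
  }
  out
}

#' Load a regulatory-variant annotation table with gene links
#'
#' The annotation TSV has columns `snp_id`, `is_regulatory`, `is_distal`
#' (yes/no), `chromatin_states`, `regulatory_elements` (`"; "`-separated,
#' `n/a` for none); the gene-link TSV has `snp_id`, `gene_symbol` (may be
#' empty), `ensembl_id`, `regulation_type`. Gene links must reference SNPs
#' present in the annotation table; a distal flag without any gene link
#' raises a consistency warning.
#'
#' @param path Annotation TSV.
#' @param gene_links_path Gene-link TSV.
#' @return A list of class `regulatory_annotations` with data.frames
#'   `annotations` and `gene_links`.
#' @export
load_annotations <- function(path, gene_links_path) {
  ann <- read_strict_tsv(path, c("snp_id", "is_regulatory", "is_distal",
                                 "chromatin_states", "regulatory_elements"),
                         "annotation")
  ann <- ann[, c("snp_id", "is_regulatory", "is_distal",
                 "chromatin_states", "regulatory_elements")]
  ann$is_regulatory <- parse_flag(ann$is_regulatory, "is_regulatory", path)
  ann$is_distal <- parse_flag(ann$is_distal, "is_distal", path)
  if (any(ann$is_distal & !ann$is_regulatory)) {
    stop("is_distal implies is_regulatory; inconsistent rows in ", path,
         call. = FALSE)
  }
  links <- read_strict_tsv(gene_links_path,
                           c("snp_id", "gene_symbol", "ensembl_id",
                             "regulation_type"), "gene-link")
  links <- links[, c("snp_id", "gene_symbol", "ensembl_id",
                     "regulation_type")]
  orphan <- setdiff(links$snp_id, ann$snp_id)
  if (length(orphan) > 0) {
    stop("gene link(s) for SNP(s) absent from the annotation table: ",
         paste(orphan, collapse = ", "), call. = FALSE)
  }
  distal_links <- unique(links$snp_id[
    links$regulation_type == "distal transcriptional regulation"])
  flagged <- ann$snp_id[ann$is_distal]
  no_link <- setdiff(flagged, distal_links)
  if (length(no_link) > 0) {
    warning("distal flag without distal gene links for: ",
            paste(no_link, collapse = ", "), call. = FALSE)
  }
  structure(list(annotations = ann, gene_links = links),
            class = "regulatory_annotations")
}

#' Write annotation tables to TSV
#'
#' Inverse of [load_annotations()]; flags are written as `yes`/`no`.
#'
#' @param annotations Annotation data.frame.
#' @param gene_links Gene-link data.frame.
#' @param path Annotation TSV path.
#' @param gene_links_path Gene-link TSV path.
#' @return Invisibly, `c(path, gene_links_path)`.
#' @export
write_annotations <- function(annotations, gene_links, path,
                              gene_links_path) {
  out <- annotations
  out$is_regulatory <- ifelse(out$is_regulatory, "yes", "no")
  out$is_distal <- ifelse(out$is_distal, "yes", "no")
  write_tsv(out, path)
  write_tsv(gene_links, gene_links_path)
  invisible(c(path, gene_links_path))
}

#' Split a multi-valued annotation cell into labels
#'
#' @param x Character vector of `"; "`-separated cells; `n/a` or empty
#'   cells give zero labels.
#' @return A list of character vectors.
#' @export
split_states <- function(x) {
  lapply(x, function(cell) {
    if (is.na(cell) || !nzchar(cell) || tolower(cell) == "n/a") {
      return(character(0))
    }
    trimws(strsplit(cell, ";", fixed = TRUE)[[1]])
  })
}

#' Validate enhancer SNPs against regulatory annotations
#'
#' Joins by exact `snp_id` match and assigns each input SNP one status:
#' `unannotated`, `annotated-nonregulatory`, `regulatory`, or
#' `regulatory-distal`. The counts satisfy
#' `n_distal <= n_regulatory <= n_annotated <= n_input`.
#'
#' @param enhancer_snps Data.frame with a `snp_id` column (e.g. from
#'   [intersect_snps()] or [make_snp_fixture()]).
#' @param annotations A `regulatory_annotations` object from
#'   [load_annotations()] or [make_annotation_fixture()] (a bare list with
#'   the same elements is accepted).
#' @return A list of class `validation_summary`: `n_input`, `n_annotated`,
#'   `n_regulatory`, `n_distal`, and `per_snp` (data.frame `snp_id`,
#'   `status`).
#' @export
validate_snps <- function(enhancer_snps, annotations) {
  ann <- annotations$annotations
  ids <- enhancer_snps$snp_id
  idx <- match(ids, ann$snp_id)
  status <- ifelse(is.na(idx), "unannotated",
            ifelse(!ann$is_regulatory[idx], "annotated-nonregulatory",
            ifelse(ann$is_distal[idx], "regulatory-distal", "regulatory")))
  structure(list(n_input = length(ids),
                 n_annotated = sum(!is.na(idx)),
                 n_regulatory = sum(ann$is_regulatory[idx], na.rm = TRUE),
                 n_distal = sum(ann$is_distal[idx], na.rm = TRUE),
                 per_snp = data.frame(snp_id = ids, status = status)),
            class = "validation_summary")
}

#' @export
print.validation_summary <- function(x, ...) {
  cat(format_validation_summary(x), sep = "\n")
  invisible(x)
}

format_validation_summary <- function(summary) {
  c("Enhancer-SNP validation summary",
    sprintf("  input SNPs:          %d", summary$n_input),
    sprintf("  annotated:           %d", summary$n_annotated),
    sprintf("  regulatory:          %d", summary$n_regulatory),
    sprintf("  distal regulation:   %d", summary$n_distal))
}

#' Write the per-SNP validation report
#'
#' Emits `<prefix>_validation.tsv` (one row per input SNP: status,
#' chromatin states, related elements, and `"; "`-joined distal target
#' genes) and `<prefix>_summary.txt` with the four counts.
#'
#' @param summary A `validation_summary` from [validate_snps()].
#' @param annotations The `regulatory_annotations` used for validation.
#' @param prefix Output path prefix.
#' @return Invisibly, a named vector with the `tsv` and `text` paths.
#' @export
write_validation_report <- function(summary, annotations, prefix) {
  ann <- annotations$annotations
  links <- annotations$gene_links
  per <- summary$per_snp
  idx <- match(per$snp_id, ann$snp_id)
  genes <- vapply(per$snp_id, function(id) {
    sub <- links[links$snp_id == id, , drop = FALSE]
    if (nrow(sub) == 0) return("")
    lab <- ifelse(nzchar(sub$gene_symbol), sub$gene_symbol, sub$ensembl_id)
    paste(lab, collapse = "; ")
  }, character(1))
  out <- data.frame(snp_id = per$snp_id,
                    status = per$status,
                    chromatin_states = ifelse(is.na(idx), "",
                                              ann$chromatin_states[idx]),
                    regulatory_elements = ifelse(is.na(idx), "",
                                                 ann$regulatory_elements[idx]),
                    target_genes = unname(genes))
  tsv <- paste0(prefix, "_validation.tsv")
  txt <- paste0(prefix, "_summary.txt")
  write_tsv(out, tsv)
  writeLines(format_validation_summary(summary), txt)
  invisible(c(tsv = tsv, text = txt))
}
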